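# Shared fixtures built in code.

## A small concentration survey config: one well-populated category.
single_category_config <- function(n_per_agency = 1000, p_d = 0.2,
                                   beta = log(2),
                                   w = c(0.5, 0.3, 0.2)) {
  np <- matrix(0, 5, 2, dimnames = list(food_categories(), agencies()))
  np["supplements", ] <- n_per_agency
  wm <- matrix(1 / 3, 5, 3)
  wm[5, ] <- w
  synth_config(n_products = np,
               true_p_d = c(0.1, 0.1, 0.1, 0.1, p_d),
               true_beta = c(0, 0, 0, 0, beta),
               bin_weights = wm,
               n_children = 1, n_adolescents = 0, n_adults = 0,
               n_missing_urine = c(0, 0, 0), n_negligible = c(0, 0, 0))
}

## Small cohort config with deterministic exclusions.
small_cohort_config <- function(n_children = 30, n_adolescents = 3,
                                n_adults = 12,
                                n_missing_urine = c(2, 0, 1),
                                n_negligible = c(0, 1, 0), ...) {
  synth_config(n_children = n_children, n_adolescents = n_adolescents,
               n_adults = n_adults, n_missing_urine = n_missing_urine,
               n_negligible = n_negligible, ...)
}

## Well-identified world for end-to-end recovery: dense survey, balanced
## mixture weights shared by all categories.
dense_world_config <- function(n_children = 160, n_adolescents = 10,
                               n_adults = 30) {
  np <- matrix(1000, 5, 2, dimnames = list(food_categories(), agencies()))
  w <- matrix(c(0.5, 0.3, 0.2), 5, 3, byrow = TRUE)
  synth_config(n_products = np, true_p_d = rep(0.3, 5),
               true_beta = log(c(2, 1, 2, 1, 2)), bin_weights = w,
               n_children = n_children, n_adolescents = n_adolescents,
               n_adults = n_adults,
               n_missing_urine = c(0, 0, 0), n_negligible = c(0, 0, 0))
}

## Hand-made record data frame.
make_records <- function(agency, category, status, value = NA,
                         product_id = NULL, concentrated = FALSE) {
  n <- max(length(agency), length(category), length(status), length(value))
  data.frame(
    agency = rep_len(agency, n), category = rep_len(category, n),
    product_id = rep_len(product_id %||% sprintf("p%03d", seq_len(n)), n),
    status = rep_len(status, n), value_ppm = rep_len(value, n),
    concentrated_flag = rep_len(concentrated, n),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## A degenerate (point-mass) fitted model whose draws are constants; every
## category returns concentration y0 for belief "yes".
point_mass_fit <- function(y0 = 10, p_d = 1) {
  posts <- lapply(food_categories(), function(cat) {
    category_posterior(p_d = p_d, w = 1, mu = log(y0), sigma = 0, p_1 = 0)
  })
  names(posts) <- food_categories()
  structure(list(categories = posts, bins = bin_scheme(1, Inf),
                 mcmc = NULL, juice_divisor = 7, sub_mean = 0.5),
            class = "conc_fit")
}

## A complete questionnaire response with every category set to `exposed`.
flat_response <- function(exposed = "no", freq = "le2", dur = "lt6m") {
  data.frame(category = food_categories(),
             exposed = exposed,
             freq_cat = ifelse(exposed == "no", NA_character_, freq),
             dur_cat = ifelse(exposed == "no", NA_character_, dur),
             stringsAsFactors = FALSE)
}
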