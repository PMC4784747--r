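#' Merge repeated measurements of the same food product
#'
#' Multiple measurements of one product (same agency and product id) are
#' collapsed to a single record: several quantified values are replaced by
#' their geometric mean, a quantified measurement dominates a censored one,
#' and any detection dominates a non-detection. Records of one product must
#' agree on the food category.
#'
#' @param records concentration-record data frame (columns `agency`,
#'   `category`, `product_id`, `status`, `value_ppm`, `concentrated_flag`).
#' @return A data frame with one row per (agency, product_id).
#' @export
#' @examples
#' r <- data.frame(agency = "TFDA", category = "tea_drinks",
#'                 product_id = "p1", status = "detected_quantified",
#'                 value_ppm = c(10, 1000), concentrated_flag = FALSE)
#' merge_product_records(r)$value_ppm  # 100 (geometric mean)
merge_product_records <- function(records) {
  key <- paste(records$agency, records$product_id, sep = "\r")
  out <- lapply(split(seq_len(nrow(records)), key), function(idx) {
    sub <- records[idx, , drop = FALSE]
    if (length(unique(sub$category)) > 1) {
      stop(sprintf("conflicting categories for product %s",
                   sub$product_id[1]), call. = FALSE)
    }
    rec <- sub[1, , drop = FALSE]
    quant <- sub$status == "detected_quantified"
    if (any(quant)) {
      rec$status <- "detected_quantified"
      rec$value_ppm <- exp(mean(log(sub$value_ppm[quant])))
      rec$concentrated_flag <- any(sub$concentrated_flag[quant])
    } else if (any(sub$status == "detected_censored")) {
      rec$status <- "detected_censored"
      rec$value_ppm <- NA_real_
    } else {
      rec$status <- "not_detected"
      rec$value_ppm <- NA_real_
    }
    rec
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$category, out$agency, out$product_id), , drop = FALSE]
}
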