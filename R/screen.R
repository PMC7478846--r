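#' Volcano-style summary of a genetic-interaction table
#'
#' Adds the negative log10 p-value, a Benjamini-Hochberg adjusted p-value
#' (for transparency; the significance call itself uses raw p-values, as
#' interaction screens are conventionally plotted), and a
#' `negative_significant` flag for aggravating interactions (epsilon < 0)
#' below the p threshold. Rows are sorted by ascending p, ties broken by
#' descending |epsilon|, which makes the order a reproducible total order.
#'
#' @param records data frame with columns `gene`, `epsilon`, `p`.
#' @param p_threshold significance threshold on the raw p-value
#'   (default 0.05).
#' @return Sorted data frame with added columns `neg_log10_p`, `p_bh`,
#'   `negative_significant`. Records with p outside (0, 1] are dropped with
#'   a warning.
#' @export
volcano_table <- function(records, p_threshold = 0.05) {
  need <- c("gene", "epsilon", "p")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  bad <- !is.finite(records$p) | records$p <= 0 | records$p > 1 |
    !is.finite(records$epsilon)
  if (any(bad)) {
    warning(sum(bad), " record(s) with invalid p or epsilon dropped")
    records <- records[!bad, , drop = FALSE]
  }
  if (!nrow(records)) {
    out <- records
    out$neg_log10_p <- numeric(0)
    out$p_bh <- numeric(0)
    out$negative_significant <- logical(0)
    return(out)
  }
  records$neg_log10_p <- -log10(records$p)
  records$p_bh <- stats::p.adjust(records$p, method = "BH")
  records$negative_significant <- records$epsilon < 0 &
    records$p < p_threshold
  ord <- order(records$p, -abs(records$epsilon))
  out <- records[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Strongest genetic interactions of the query gene
#'
#' Top k records under the volcano ranking (ascending p, ties by
#' descending |epsilon|).
#'
#' @param records data frame with columns `gene`, `epsilon`, `p`.
#' @param k number of records (k >= 1); a k beyond the table returns the
#'   whole table.
#' @return Ranked data frame of at most k rows.
#' @export
#' @examples
#' top_interactions(simulate_screen(), 2)$gene  # GNP1 and YDR509W
top_interactions <- function(records, k) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1)
  vt <- volcano_table(records)
  utils::head(vt, k)
}
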