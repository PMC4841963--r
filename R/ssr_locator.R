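# SSR localization relative to the predicted principal ORF.

#' Localize SSR hits to 5'UTR / ORF / 3'UTR / Other
#'
#' A tract fully inside the ORF interval is \code{ORF}; fully on the 5'
#' side of the ORF (strand-aware) is \code{FIVE_UTR}; fully on the 3'
#' side is \code{THREE_UTR}. Tracts straddling an ORF boundary, and all
#' tracts on transcripts without an annotated ORF, go to \code{OTHER} —
#' the "no precise position" bucket. On the minus strand the upstream
#' transcript end is the 3' side, so FIVE_UTR/THREE_UTR swap.
#'
#' @param hits SSR hit frame (\code{\link{find_ssrs}}).
#' @param orfs ORF frame (\code{\link{read_orf_bed}}); at most one per
#'   transcript.
#' @return \code{hits} with a \code{localization} column.
#' @export
locate_ssrs <- function(hits, orfs) {
  if (anyDuplicated(orfs$transcript_id)) {
    stop("more than one ORF per transcript")
  }
  idx <- match(hits$transcript_id, orfs$transcript_id)
  loc <- vapply(seq_len(nrow(hits)), function(i) {
    j <- idx[i]
    if (is.na(j)) return("OTHER")
    s <- hits$start[i]; e <- hits$end[i]
    os <- orfs$start[j]; oe <- orfs$end[j]
    if (s >= os && e <= oe) return("ORF")
    left <- e <= os   # fully between transcript start and ORF
    right <- s >= oe  # fully between ORF and transcript end
    if (!left && !right) return("OTHER")  # straddles a boundary
    if (orfs$strand[j] == "+") {
      if (left) "FIVE_UTR" else "THREE_UTR"
    } else {
      if (left) "THREE_UTR" else "FIVE_UTR"
    }
  }, character(1))
  hits$localization <- loc
  hits
}

#' Tabulate SSR localization by motif class
#'
#' Counts per (category x class) with row percentages, plus each
#' category's share of all SSRs — the localization summary table.
#'
#' @param hits Localized SSR frame (\code{\link{locate_ssrs}}).
#' @param mode Rounding mode for percentages.
#' @return data.frame with one row per category (FIVE_UTR, ORF,
#'   THREE_UTR, OTHER) plus a Total row; columns \code{n_di, pct_di,
#'   n_tri, pct_tri, n_tetra, pct_tetra, n_total, pct_total}.
#' @export
summarize_localization <- function(hits, mode = "round") {
  if (is.null(hits$localization)) stop("hits are not localized")
  cats <- c("FIVE_UTR", "ORF", "THREE_UTR", "OTHER")
  klasses <- c("di", "tri", "tetra")
  total <- nrow(hits)
  rows <- lapply(cats, function(cat) {
    h <- hits[hits$localization == cat, , drop = FALSE]
    n_k <- vapply(klasses, function(k) sum(h$klass == k), integer(1))
    pct_k <- if (nrow(h) > 0) percent_1dp(n_k, nrow(h), mode) else rep(NA_real_, 3)
    data.frame(category = cat,
               n_di = n_k[1], pct_di = pct_k[1],
               n_tri = n_k[2], pct_tri = pct_k[2],
               n_tetra = n_k[3], pct_tetra = pct_k[3],
               n_total = nrow(h),
               pct_total = if (total > 0) percent_1dp(nrow(h), total, mode) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  tot_k <- vapply(klasses, function(k) sum(hits$klass == k), integer(1))
  out <- rbind(out, data.frame(
    category = "Total",
    n_di = tot_k[1],
    pct_di = if (total > 0) percent_1dp(tot_k[1], total, mode) else NA_real_,
    n_tri = tot_k[2],
    pct_tri = if (total > 0) percent_1dp(tot_k[2], total, mode) else NA_real_,
    n_tetra = tot_k[3],
    pct_tetra = if (total > 0) percent_1dp(tot_k[3], total, mode) else NA_real_,
    n_total = total, pct_total = if (total > 0) 100.0 else NA_real_,
    stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
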