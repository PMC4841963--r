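# Derived summary quantities: unigene selection from isoform clusters,
# splice-variant fraction, length distributions, percent formatting.

#' One-decimal percentage with explicit rounding mode
#'
#' \code{mode = "round"} uses round-half-even (R's \code{round});
#' \code{mode = "truncate"} drops digits beyond the first decimal.
#' Published tables mix both behaviours, so the mode is explicit and the
#' raw ratio is always recoverable from the inputs.
#'
#' @param num,den Numerator(s) and denominator.
#' @param mode \code{"round"} or \code{"truncate"}.
#' @return numeric vector of percentages with one decimal.
#' @export
percent_1dp <- function(num, den, mode = c("round", "truncate")) {
  mode <- match.arg(mode)
  x <- 100 * num / den
  if (mode == "round") round(x, 1) else trunc(x * 10) / 10
}

#' Select one representative unigene per isoform cluster
#'
#' Keeps, for every cluster (assembled locus), the single most-expressed
#' transcript; ties break to the lexicographically smallest transcript
#' id. Expression units are opaque — only the ordering matters.
#'
#' @param records data.frame with \code{transcript_id, cluster_id,
#'   expression} (one row per transcript).
#' @return character vector of selected transcript ids, one per cluster,
#'   sorted.
#' @export
select_unigenes <- function(records) {
  stopifnot(all(c("transcript_id", "cluster_id", "expression") %in%
                  colnames(records)))
  if (anyDuplicated(records$transcript_id)) {
    stop("duplicate transcript_id in expression records")
  }
  if (any(records$expression < 0)) stop("negative expression value")
  o <- order(records$cluster_id, -records$expression, records$transcript_id)
  r <- records[o, , drop = FALSE]
  sort(r$transcript_id[!duplicated(r$cluster_id)])
}

#' Fraction of transcripts that are splice variants
#'
#' The redundancy removed by unigene selection:
#' \code{100 * (n_transcripts - n_unigenes) / n_transcripts}, one
#' decimal.
#'
#' @param n_transcripts Total assembled transcripts.
#' @param n_unigenes Unigenes retained after per-cluster selection.
#' @param mode Rounding mode (see \code{\link{percent_1dp}}).
#' @return percentage with one decimal.
#' @export
splice_variant_fraction <- function(n_transcripts, n_unigenes,
                                    mode = "round") {
  if (n_transcripts <= 0) stop("n_transcripts must be positive")
  if (n_unigenes > n_transcripts) stop("more unigenes than transcripts")
  percent_1dp(n_transcripts - n_unigenes, n_transcripts, mode)
}

#' Binned length distribution with exact min/max/mean
#'
#' @param lengths Integer lengths (transcripts or SSR tracts), or a named
#'   sequence set whose widths are used.
#' @param breaks Right-closed bin upper bounds; an implicit final bin
#'   catches everything larger. Default matches the usual transcriptome
#'   report bins (201-500, 501-1000, >1000 for sequences >= 201 nt).
#' @return list with \code{bins} (data.frame label/n), \code{min},
#'   \code{max}, \code{mean}.
#' @export
length_histogram <- function(lengths, breaks = c(200, 500, 1000)) {
  if (!is.numeric(lengths)) lengths <- nchar(as.character(lengths))
  if (length(lengths) == 0L) stop("empty input")
  breaks <- sort(breaks)
  edges <- c(-Inf, breaks, Inf)
  lab <- c(paste0("<=", breaks[1]),
           if (length(breaks) > 1)
             paste0(breaks[-length(breaks)] + 1, "-", breaks[-1]),
           paste0(">", breaks[length(breaks)]))
  cnt <- as.integer(table(cut(lengths, edges, labels = lab)))
  list(bins = data.frame(label = lab, n = cnt, stringsAsFactors = FALSE),
       min = min(lengths), max = max(lengths), mean = mean(lengths))
}

#' Sum SNP and INDEL counts into a category total
#'
#' The kind split partitions every category, so the category total is
#' the plain sum; kept as an operation so reported tables are always
#' internally consistent.
#'
#' @param indels,snps Non-negative counts.
#' @return integer total.
#' @export
snv_total <- function(indels, snps) {
  stopifnot(all(indels >= 0), all(snps >= 0))
  as.integer(indels + snps)
}

#' Read a transcript-cluster expression table
#'
#' TSV with columns \code{transcript_id, cluster_id, expression}.
#' @param path TSV path.
#' @return data.frame.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("expression table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("transcript_id", "cluster_id", "expression") %in%
                  colnames(df)))
  df$expression <- as.numeric(df$expression)
  df
}
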