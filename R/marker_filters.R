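# Genotyping-suitability filter cascade: CS60 (SNV spacing), CL60 (edge
# distance), HV0.05 (SNV density), CEF (CAPS by differential restriction
# digestion). A marker is "filtered" (retained) when it is well spaced,
# away from the transcript edges, outside high-variability regions and
# digestible differentially by at least one catalogue enzyme.

#' Flag variants closer than a threshold to another variant (CS60)
#'
#' Distance is measured between the 0-based offsets of the first REF
#' bases on the same transcript. "Closer than" is strict: distance 59
#' flags, distance 60 passes.
#'
#' @param v Variant frame.
#' @param threshold Minimum clear spacing in nt (default 60).
#' @return logical vector, one flag per record.
#' @export
flag_cs60 <- function(v, threshold = 60L) {
  flags <- logical(nrow(v))
  for (tid in unique(v$transcript_id)) {
    idx <- which(v$transcript_id == tid)
    if (length(idx) < 2L) next
    p <- v$pos[idx]
    o <- order(p)
    ps <- p[o]
    d <- diff(ps)
    near <- logical(length(ps))
    near[-length(ps)] <- d < threshold
    near[-1] <- near[-1] | (d < threshold)
    flags[idx[o]] <- near
  }
  flags
}

#' Flag variants closer than a threshold to a transcript edge (CL60)
#'
#' Edge distance is \code{min(pos, length - 1 - pos)} on the first REF
#' base; strict "closer than".
#'
#' @param v Variant frame.
#' @param transcript_lengths Named integer vector (or named sequences) of
#'   transcript lengths.
#' @param threshold Minimum edge distance in nt (default 60).
#' @return logical vector.
#' @export
flag_cl60 <- function(v, transcript_lengths, threshold = 60L) {
  if (!is.numeric(transcript_lengths)) {
    transcript_lengths <- stats::setNames(nchar(as.character(transcript_lengths)),
                                          names(transcript_lengths))
  }
  len <- transcript_lengths[v$transcript_id]
  if (anyNA(len)) {
    stop("transcript length missing for: ",
         paste(unique(v$transcript_id[is.na(len)]), collapse = ", "))
  }
  pmin(v$pos, len - 1L - v$pos) < threshold
}

#' Flag variants in high-variability regions (HV0.05)
#'
#' A variant is flagged when some sliding window of \code{window} nt
#' containing it holds strictly more than \code{max_snvs} variants (the
#' variant itself included): equivalently, when it belongs to a set of
#' \code{max_snvs + 1} variants spanning at most \code{window - 1} nt.
#'
#' @param v Variant frame.
#' @param window Window size in nt (default 100).
#' @param max_snvs Maximum variants tolerated per window (default 5).
#' @return logical vector.
#' @export
flag_hv <- function(v, window = 100L, max_snvs = 5L) {
  flags <- logical(nrow(v))
  need <- max_snvs + 1L
  for (tid in unique(v$transcript_id)) {
    idx <- which(v$transcript_id == tid)
    if (length(idx) < need) next
    o <- order(v$pos[idx])
    ps <- v$pos[idx][o]
    n <- length(ps)
    fl <- logical(n)
    for (j in seq_len(n - need + 1L)) {
      if (ps[j + need - 1L] - ps[j] <= window - 1L) fl[j:(j + need - 1L)] <- TRUE
    }
    flags[idx[o]] <- fl
  }
  flags
}

iupac_regex <- function(site) {
  paste(vapply(strsplit(site, "")[[1]], function(ch) {
    cl <- iupac_classes[[ch]]
    if (is.null(cl)) stop("not an IUPAC code: ", ch)
    if (length(cl) == 1L) cl else paste0("[", paste(cl, collapse = ""), "]")
  }, character(1)), collapse = "")
}

regex_starts <- function(rx, subject) {
  # all (overlapping) match starts via zero-width lookahead
  m <- gregexpr(paste0("(?=", rx, ")"), subject, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

iupac_match_starts <- function(site, subject) {
  # start positions of IUPAC `site` on both strands of `subject`
  if (nchar(subject) < nchar(site)) return(integer(0))
  fwd <- regex_starts(iupac_regex(site), subject)
  rcs <- revcomp_chr(site)
  rev <- if (rcs == site) integer(0) else {
    regex_starts(iupac_regex(rcs), subject)
  }
  sort(unique(c(fwd, rev)))
}

fragment_pattern <- function(site, subject) {
  cuts <- iupac_match_starts(site, subject)
  sort(diff(c(0L, cuts, nchar(subject) + 1L)))
}

# precompiled both-strand regexes for a catalogue
compile_enzymes <- function(enzymes) {
  lapply(seq_len(nrow(enzymes)), function(j) {
    site <- enzymes$site[j]
    rcs <- revcomp_chr(site)
    list(name = enzymes$name[j],
         rx = unique(c(iupac_regex(site), iupac_regex(rcs))))
  })
}

fragment_pattern_rx <- function(rx, subject) {
  cuts <- sort(unique(unlist(lapply(rx, regex_starts, subject = subject))))
  sort(diff(c(0L, cuts, nchar(subject) + 1L)))
}

# Allelic context pair around one variant: ±flank nt, truncated at edges.
allele_contexts <- function(seq, pos, ref, alt1, flank) {
  n <- nchar(seq)
  left <- substr(seq, max(1L, pos + 1L - flank), pos)
  right_start <- pos + 1L + nchar(ref)
  right <- if (right_start > n) "" else {
    substr(seq, right_start, min(n, pos + nchar(ref) + flank))
  }
  list(ref = paste0(left, ref, right), alt = paste0(left, alt1, right))
}

#' Flag variants genotypable as CAPS markers (CEF)
#'
#' For each variant, the two allelic context sequences (±\code{flank} nt
#' around the site, the amplicon a CAPS assay would cut) are digested in
#' silico with every catalogue enzyme, matching IUPAC recognition sites
#' on both strands. The variant passes when some enzyme produces a
#' different fragment pattern on the REF context than on an ALT context —
#' the allele difference creates or destroys (or moves) a recognition
#' site, so the digest distinguishes the alleles on a gel. Multi-allelic
#' sites pass if any ALT is differential.
#'
#' @param v Variant frame.
#' @param seqs Transcript sequences (named \code{DNAStringSet} or
#'   character vector).
#' @param enzymes Enzyme catalogue (\code{\link{read_enzymes}}).
#' @param flank Context half-width in nt (default 60, matching the
#'   small-amplicon spacing rules).
#' @return list with \code{cef_pass} (logical) and \code{cef_enzymes}
#'   (comma-joined names of differential enzymes, "" when none).
#' @export
flag_cef <- function(v, seqs, enzymes, flank = 60L) {
  if (!is.character(seqs)) seqs <- stats::setNames(as.character(seqs), names(seqs))
  pass <- logical(nrow(v)); enz <- character(nrow(v))
  alts <- split_alts(v$alt)
  compiled <- compile_enzymes(enzymes)
  for (i in seq_len(nrow(v))) {
    s <- seqs[[v$transcript_id[i]]]
    if (is.null(s) || is.na(s)) stop("transcript not found: ", v$transcript_id[i])
    hits <- character(0)
    for (a in alts[[i]]) {
      ctx <- allele_contexts(s, v$pos[i], v$ref[i], a, flank)
      for (e in compiled) {
        if (e$name %in% hits) next
        if (!identical(fragment_pattern_rx(e$rx, ctx$ref),
                       fragment_pattern_rx(e$rx, ctx$alt))) {
          hits <- c(hits, e$name)
        }
      }
    }
    pass[i] <- length(hits) > 0L
    enz[i] <- paste(sort(hits), collapse = ",")
  }
  list(cef_pass = pass, cef_enzymes = enz)
}

#' Apply the full marker-suitability cascade
#'
#' Computes CS60, CL60, HV0.05 and CEF flags and the combined
#' \code{filtered} verdict: retained iff not CS60-, CL60- or HV-flagged
#' and CEF passes.
#'
#' @param v Variant frame (tags from \code{\link{classify_species}} may
#'   or may not be present).
#' @param seqs Transcript sequences.
#' @param enzymes Enzyme catalogue; default the packaged one.
#' @param cs,cl CS60/CL60 distance thresholds in nt.
#' @param hv_window,hv_max HV window size and maximum variants per window.
#' @param flank CEF context half-width in nt.
#' @return \code{v} with columns \code{cs60, cl60, hv, cef_pass,
#'   cef_enzymes, filtered}.
#' @export
apply_filters <- function(v, seqs, enzymes = read_enzymes(), cs = 60L,
                          cl = 60L, hv_window = 100L, hv_max = 5L,
                          flank = 60L) {
  lens <- stats::setNames(nchar(as.character(seqs)), names(seqs))
  v$cs60 <- flag_cs60(v, cs)
  v$cl60 <- flag_cl60(v, lens, cl)
  v$hv <- flag_hv(v, hv_window, hv_max)
  cef <- flag_cef(v, seqs, enzymes, flank)
  v$cef_pass <- cef$cef_pass
  v$cef_enzymes <- cef$cef_enzymes
  v$filtered <- !v$cs60 & !v$cl60 & !v$hv & v$cef_pass
  v
}
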