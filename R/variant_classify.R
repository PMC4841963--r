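# SNV classification: SNP/INDEL kind split and intraspecific /
# interspecific tagging from per-species genotypes.

split_alts <- function(alt) strsplit(alt, ",", fixed = TRUE)

#' Classify variant kind (SNP vs INDEL)
#'
#' A site is a SNP iff REF is a single base and every ALT allele is a
#' single base; anything else (insertion, deletion, MNP-style allele) is
#' an INDEL — the "is not a SNP" split.
#'
#' @param v Variant frame (\code{\link{read_vcf}}).
#' @return character vector \code{"SNP"}/\code{"INDEL"}, one per record.
#' @export
classify_kind <- function(v) {
  alts <- split_alts(v$alt)
  vapply(seq_len(nrow(v)), function(i) {
    if (nchar(v$ref[i]) == 1L && all(nchar(alts[[i]]) == 1L)) "SNP" else "INDEL"
  }, character(1))
}

# Per-species genotype status for one record.
# Returns list(status = "hom"|"het"|"none", allele = index or NA) per species.
species_status <- function(gts) {
  pairs <- lapply(gts, function(g) {
    a <- strsplit(g, "[/|]")[[1]]
    if (length(a) == 1L) a <- c(a, a)  # haploid call counts as hom
    a
  })
  called <- vapply(pairs, function(a) !any(a == "."), logical(1))
  pairs <- pairs[called]
  if (length(pairs) == 0L) return(list(status = "none", allele = NA_integer_))
  if (any(vapply(pairs, function(a) a[1] != a[2], logical(1)))) {
    return(list(status = "het", allele = NA_integer_))
  }
  al <- unique(vapply(pairs, `[`, character(1), 1))
  if (length(al) == 1L) {
    list(status = "hom", allele = as.integer(al))
  } else {
    # samples of one species homozygous for different alleles: neither
    # heterozygous nor "homozygous for a specific allele"
    list(status = "none", allele = NA_integer_)
  }
}

all_species_combos <- function(species) {
  species <- sort(species)
  unlist(lapply(2:length(species), function(k) {
    utils::combn(species, k, FUN = function(s) paste(s, collapse = "+"))
  }), use.names = FALSE)
}

#' Tag variants as intraspecific and/or interspecific
#'
#' A species is tagged intraspecific at a site when it carries a called
#' heterozygous genotype. A species combination (any subset of 2 or more
#' species) is tagged interspecific when every member species is
#' homozygous for a called allele and at least two distinct alleles occur
#' among the members — homozygous within species, differential between
#' them. With several samples per species, the species is homozygous for
#' allele a only if all its called samples are a/a, and heterozygous if
#' any sample is het. A missing genotype excludes the species from every
#' tag. The two tag kinds are independent: a site het in one species can
#' still be interspecific for a combination of others.
#'
#' @param v Variant frame.
#' @param panel Species panel mapping samples to species.
#' @return \code{v} with columns \code{kind}, \code{intraspecific}
#'   (comma-joined species ids) and \code{interspecific} (semicolon-joined
#'   combinations, each \code{"SP1+SP2[+...]"} with members sorted).
#' @export
classify_species <- function(v, panel) {
  samples <- attr(v, "samples")
  if (is.null(samples)) samples <- intersect(colnames(v), panel$sample_id)
  missing_samples <- setdiff(samples, panel$sample_id)
  if (length(missing_samples) > 0L) {
    stop("sample(s) absent from panel: ", paste(missing_samples, collapse = ", "))
  }
  species <- sort(unique(panel$species_id))
  by_sp <- lapply(species, function(sp) {
    intersect(samples, panel$sample_id[panel$species_id == sp])
  })
  names(by_sp) <- species
  subsets <- unlist(lapply(2:max(2L, length(species)), function(k) {
    if (k > length(species)) return(NULL)
    utils::combn(species, k, simplify = FALSE)
  }), recursive = FALSE)
  n <- nrow(v)
  gtm <- as.matrix(v[, samples, drop = FALSE])
  intra <- character(n); inter <- character(n)
  for (i in seq_len(n)) {
    st <- lapply(by_sp, function(ss) species_status(gtm[i, ss]))
    intra[i] <- paste(
      species[vapply(st, function(s) s$status == "het", logical(1))],
      collapse = ",")
    tags <- vapply(subsets, function(sub) {
      s <- st[sub]
      if (!all(vapply(s, function(x) x$status == "hom", logical(1)))) return(NA_character_)
      if (length(unique(vapply(s, `[[`, integer(1), "allele"))) < 2L) return(NA_character_)
      paste(sub, collapse = "+")
    }, character(1))
    inter[i] <- paste(tags[!is.na(tags)], collapse = ";")
  }
  v$kind <- classify_kind(v)
  v$intraspecific <- intra
  v$interspecific <- inter
  v
}

#' SNV summary by category (intraspecific species / interspecific combo)
#'
#' For each intraspecific species and each 2-, 3- and 4-way species
#' combination, counts INDELs, SNPs, their total, and — when filter flags
#' are present — how many survive the full suitability cascade.
#'
#' @param v Tagged variant frame (\code{\link{classify_species}}, and
#'   optionally \code{\link{apply_filters}}).
#' @param panel Species panel.
#' @return data.frame with \code{category, type} ("intraspecific" /
#'   "interspecific"), \code{indels, snps, total} and \code{filtered}
#'   (NA when flags are absent).
#' @export
count_by_category <- function(v, panel) {
  species <- sort(unique(panel$species_id))
  has_filt <- "filtered" %in% colnames(v)
  intra_sets <- if (nrow(v) > 0L) strsplit(v$intraspecific, ",", fixed = TRUE) else list()
  inter_sets <- if (nrow(v) > 0L) strsplit(v$interspecific, ";", fixed = TRUE) else list()
  one <- function(category, type, sel) {
    data.frame(
      category = category, type = type,
      indels = sum(sel & v$kind == "INDEL"),
      snps = sum(sel & v$kind == "SNP"),
      total = sum(sel),
      filtered = if (has_filt) sum(sel & v$filtered) else NA_integer_,
      stringsAsFactors = FALSE)
  }
  rows <- lapply(species, function(sp) {
    sel <- vapply(intra_sets, function(s) sp %in% s, logical(1))
    if (length(sel) == 0L) sel <- logical(0)
    one(sp, "intraspecific", sel)
  })
  combos <- if (length(species) >= 2L) all_species_combos(species) else character(0)
  rows <- c(rows, lapply(combos, function(cb) {
    sel <- vapply(inter_sets, function(s) cb %in% s, logical(1))
    if (length(sel) == 0L) sel <- logical(0)
    one(cb, "interspecific", sel)
  }))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
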