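#' Read transcript sequences from a FASTA file
#'
#' Transcripts are the coordinate frame for every downstream operation:
#' ORFs, SSR tracts and variant positions are all expressed as 0-based,
#' half-open offsets on these sequences. Sequences are uppercased on
#' ingest; bases outside \{A,C,G,T,N\} are rejected.
#'
#' @param path Path to a (plain-text) FASTA file.
#' @return A named \code{\link[Biostrings]{DNAStringSet}}, one element per
#'   record, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate transcript id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  if (any(Biostrings::width(seqs) == 0L)) {
    stop("empty sequence(s) in ", path, ": ",
         paste(ids[Biostrings::width(seqs) == 0L], collapse = ", "))
  }
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  names(seqs) <- ids
  seqs
}

#' Write transcript sequences to FASTA
#'
#' @param seqs Named \code{DNAStringSet} or named character vector.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  con <- file(path, "wb")  # binary mode: byte-identical across platforms
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    s <- as.character(seqs[[i]])
    chunks <- substring(s, seq(1L, nchar(s), width),
                        pmin(seq(1L, nchar(s), width) + width - 1L, nchar(s)))
    writeLines(c(paste0(">", names(seqs)[i]), chunks), con, sep = "\n")
  }
  invisible(path)
}

#' Read ORF annotations from BED
#'
#' Consumes BED (0-based, half-open) with a strand column; at most one
#' principal ORF per transcript is allowed. Coordinates are kept 0-based
#' half-open, the package-wide convention.
#'
#' @param path BED file (>= 6 columns, or 4 columns chrom/start/end/strand).
#' @return data.frame with columns \code{transcript_id, start, end, strand}.
#' @export
read_orf_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  orfs <- data.frame(
    transcript_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # GRanges is 1-based closed
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  if (any(orfs$strand == "*")) {
    stop("ORF BED records must carry a +/- strand: ", path)
  }
  dup <- orfs$transcript_id[duplicated(orfs$transcript_id)]
  if (length(dup) > 0L) {
    stop("more than one ORF for transcript(s): ",
         paste(unique(dup), collapse = ", "))
  }
  if (any(orfs$start >= orfs$end) || any(orfs$start < 0L)) {
    stop("invalid ORF interval(s) in ", path)
  }
  orfs
}

#' Write ORF annotations as BED6
#' @param orfs data.frame as returned by \code{read_orf_bed}.
#' @param path Output path.
#' @export
write_orf_bed <- function(orfs, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   orfs$transcript_id, orfs$start, orfs$end,
                   paste0(orfs$transcript_id, "_orf"), orfs$strand)
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a sample-to-species panel
#'
#' Two-column TSV (\code{sample_id}, \code{species_id}) mapping each VCF
#' sample column to the species it represents. Several samples may map to
#' one species; every declared species needs at least one sample.
#'
#' @param path TSV path (header optional; detected by column names).
#' @return data.frame with columns \code{sample_id, species_id}.
#' @export
read_species_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", comment.char = "#")
  if (ncol(df) < 2L) stop("panel must have two columns: sample_id, species_id")
  if (identical(tolower(df[1, 1]), "sample_id")) df <- df[-1, , drop = FALSE]
  panel <- data.frame(sample_id = df[[1]], species_id = df[[2]],
                      stringsAsFactors = FALSE)
  if (anyDuplicated(panel$sample_id)) {
    stop("duplicate sample_id in panel: ",
         paste(panel$sample_id[duplicated(panel$sample_id)], collapse = ", "))
  }
  panel
}

#' Write a species panel TSV
#' @param panel data.frame with \code{sample_id, species_id}.
#' @param path Output path.
#' @export
write_species_panel <- function(panel, path) {
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(c("sample_id\tspecies_id",
               sprintf("%s\t%s", panel$sample_id, panel$species_id)),
             con, sep = "\n")
  invisible(path)
}

gt_pattern <- "^(\\.|[0-9]+)([/|](\\.|[0-9]+))?$"

#' Read a multi-sample VCF into a variant frame
#'
#' Positions are converted from VCF's 1-based convention to the package's
#' 0-based offsets at this boundary (and only here). Multi-allelic sites
#' are kept intact; missing genotypes stay \code{"./."}. Every sample
#' column must be present in the panel.
#'
#' @param path Uncompressed VCF (v4.x) with a GT FORMAT field.
#' @param panel Species panel data.frame (see \code{read_species_panel}).
#' @return A "variant frame": data.frame with \code{transcript_id, pos}
#'   (0-based), \code{ref, alt} (comma-separated ALTs) and one genotype
#'   column per sample, named by sample id. Sample names are stored in
#'   \code{attr(., "samples")}.
#' @export
read_vcf <- function(path, panel) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- VariantAnnotation::readVcf(path, genome = "transcriptome")
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  samples <- colnames(gt)
  missing_samples <- setdiff(samples, panel$sample_id)
  if (length(missing_samples) > 0L) {
    stop("VCF sample(s) absent from panel: ",
         paste(missing_samples, collapse = ", "))
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  alts <- vapply(
    as.list(VariantAnnotation::fixed(vcf)$ALT),
    function(a) paste(as.character(a), collapse = ","), character(1))
  v <- data.frame(
    transcript_id = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr) - 1L,  # 1-based -> 0-based
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = alts,
    stringsAsFactors = FALSE
  )
  bad <- !grepl(gt_pattern, gt)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)
    stop(sprintf("malformed GT '%s' at record %d (sample %s) in %s",
                 gt[idx[1, 1], idx[1, 2]], idx[1, 1],
                 samples[idx[1, 2]], path))
  }
  for (s in samples) v[[s]] <- unname(gt[, s])
  rownames(v) <- NULL
  attr(v, "samples") <- samples
  v
}

#' Write a variant frame as VCF v4.2
#'
#' Inverse of \code{\link{read_vcf}}: 0-based positions go back to
#' 1-based POS. Classification tags and filter flags, when present, are
#' serialized into INFO/FILTER so an annotated copy can be shared.
#'
#' @param v Variant frame.
#' @param path Output path.
#' @export
write_vcf <- function(v, path) {
  samples <- attr(v, "samples")
  if (is.null(samples)) {
    samples <- setdiff(colnames(v), c(
      "transcript_id", "pos", "ref", "alt", "kind", "intraspecific",
      "interspecific", "cs60", "cl60", "hv", "cef_pass", "cef_enzymes",
      "filtered"))
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=genepoolmarkers",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  has_tags <- all(c("intraspecific", "interspecific") %in% colnames(v))
  has_flags <- "filtered" %in% colnames(v)
  if (has_tags) {
    hdr <- c(hdr,
      '##INFO=<ID=INTRA,Number=.,Type=String,Description="Intraspecific (heterozygous) species">',
      '##INFO=<ID=INTER,Number=.,Type=String,Description="Interspecific homozygous-differential species combinations">')
  }
  if (has_flags) {
    hdr <- c(hdr,
      '##FILTER=<ID=CS60,Description="Another SNV closer than 60 nt">',
      '##FILTER=<ID=CL60,Description="Closer than 60 nt to a transcript edge">',
      '##FILTER=<ID=HV,Description="More than 5 SNVs per 100 nt window">',
      '##FILTER=<ID=CEF,Description="No differential restriction enzyme">')
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", samples),
                      collapse = "\t"))
  filt <- rep("PASS", nrow(v))
  if (has_flags && nrow(v) > 0L) {
    filt <- vapply(seq_len(nrow(v)), function(i) {
      f <- c(if (isTRUE(v$cs60[i])) "CS60", if (isTRUE(v$cl60[i])) "CL60",
             if (isTRUE(v$hv[i])) "HV", if (!isTRUE(v$cef_pass[i])) "CEF")
      if (length(f) == 0L) "PASS" else paste(f, collapse = ";")
    }, character(1))
  }
  info <- rep(".", nrow(v))
  if (has_tags && nrow(v) > 0L) {
    info <- vapply(seq_len(nrow(v)), function(i) {
      f <- c(
        if (nzchar(v$intraspecific[i])) paste0("INTRA=", v$intraspecific[i]),
        if (nzchar(v$interspecific[i]))
          paste0("INTER=", gsub(";", ",", v$interspecific[i])))
      if (length(f) == 0L) "." else paste(f, collapse = ";")
    }, character(1))
  }
  gt_cols <- if (nrow(v) > 0L) {
    do.call(paste, c(lapply(samples, function(s) v[[s]]), sep = "\t"))
  } else character(0)
  body <- if (nrow(v) > 0L) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s\tGT\t%s",
            v$transcript_id, v$pos + 1L, v$ref, v$alt, filt, info, gt_cols)
  } else character(0)
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(c(hdr, body), con, sep = "\n")
  invisible(path)
}

#' Write an annotated marker table as TSV
#'
#' One row per marker (variant or SSR hit), deterministic column order,
#' logicals serialized as TRUE/FALSE. Round-trips through
#' \code{\link{read_marker_table}}.
#'
#' @param records data.frame of annotated markers.
#' @param path Output path.
#' @export
write_marker_table <- function(records, path) {
  con <- try(file(path, "wb"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write to ", path)
  on.exit(close(con))
  cols <- colnames(records)
  lines <- paste(cols, collapse = "\t")
  if (nrow(records) > 0L) {
    cells <- lapply(cols, function(cn) {
      x <- records[[cn]]
      if (is.logical(x)) ifelse(x, "TRUE", "FALSE")
      else if (is.numeric(x) && !is.integer(x)) format(x, digits = 15, trim = TRUE)
      else as.character(x)
    })
    lines <- c(lines, do.call(paste, c(cells, sep = "\t")))
  }
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a marker table written by \code{write_marker_table}
#' @param path TSV path.
#' @return data.frame with logical/integer/numeric columns restored.
#' @export
read_marker_table <- function(path) {
  if (!file.exists(path)) stop("marker table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  for (cn in colnames(df)) {
    x <- df[[cn]]
    if (all(x %in% c("TRUE", "FALSE"))) df[[cn]] <- as.logical(x)
    else if (length(x) > 0L && all(grepl("^-?[0-9]+$", x))) df[[cn]] <- as.integer(x)
    else if (length(x) > 0L &&
             all(grepl("^-?[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?$", x)))
      df[[cn]] <- as.numeric(x)
  }
  df
}

#' Load a restriction-enzyme catalogue
#'
#' TSV with columns \code{name}, \code{site} (IUPAC recognition sequence)
#' and \code{common} (logical: member of the low-priced set used for CAPS
#' genotyping). With no argument the packaged catalogue of ~20 common
#' 6-cutters is returned.
#'
#' @param path Optional TSV path; default is the packaged catalogue.
#' @return data.frame with \code{name, site, common}.
#' @export
read_enzymes <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "enzymes_common6.tsv",
                        package = "genepoolmarkers", mustWork = TRUE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "site") %in% colnames(df)))
  if (is.null(df$common)) df$common <- TRUE
  df$site <- toupper(df$site)
  bad <- !grepl("^[ACGTRYSWKMBDHVN]+$", df$site) | nchar(df$site) < 4L
  if (any(bad)) {
    stop("invalid recognition site(s): ", paste(df$name[bad], collapse = ", "))
  }
  df[, c("name", "site", "common")]
}
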