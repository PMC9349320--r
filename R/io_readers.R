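#' @name io-formats
#' @title Input file dialects
#' @description
#' All tables are plain tab-separated files with a header row, and all
#' genomic coordinates are 1-based inclusive.
#' \itemize{
#'   \item Mutation table: columns \code{variant_id chrom pos ref alt gene}
#'     (optionally \code{context96}, the 0-based trinucleotide class),
#'     followed by per-sample pairs \code{<sample>:alt} and
#'     \code{<sample>:depth} (optionally \code{<sample>:qc} with
#'     TRUE/FALSE; missing qc columns default to TRUE).
#'   \item Copy-number segments (SEG-like): \code{sample chrom start end
#'     total_cn minor_cn}.
#'   \item Sample sheet: \code{sample_id patient_id site_class
#'     anatomical_label timepoint purity}.
#'   \item Signature catalog: COSMIC-format, 96 rows, a \code{Type} column
#'     like \code{"A[C>A]A"} plus one column per signature.
#'   \item Clinical table: \code{patient_id pet_fl_count best_response}
#'     and optionally \code{gep70_score}.
#' }
NULL

SITE_CLASSES <- c("iliac_crest_left", "iliac_crest_right", "focal_lesion",
                  "soft_tissue", "peripheral_blood")
RESPONSES <- c("CR", "VGPR", "PR", "SD", "PD")

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path))
    stop_mmclone("file not found: ", path, class = "mmclone_format_error")
  x <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                  stringsAsFactors = FALSE, comment.char = "#")
  miss <- setdiff(required, names(x))
  if (length(miss))
    stop_mmclone(what, ": missing required column(s): ",
                 paste(miss, collapse = ", "),
                 class = "mmclone_format_error")
  x
}

#' Read a sample sheet
#'
#' @param path Path to a tab-separated sample sheet (see
#'   \link{io-formats}).
#' @return A data.frame with one row per sample: \code{sample_id},
#'   \code{patient_id}, \code{site_class}, \code{anatomical_label},
#'   \code{timepoint} (ordinal treatment-line index, 0 = baseline) and
#'   \code{purity} in (0, 1].
#' @export
read_sample_sheet <- function(path) {
  x <- read_tsv_checked(path, c("sample_id", "patient_id", "site_class",
                                "timepoint", "purity"), "sample sheet")
  if (is.null(x$anatomical_label)) x$anatomical_label <- ""
  bad <- !(x$site_class %in% SITE_CLASSES)
  if (any(bad))
    stop_mmclone("sample sheet: unknown site_class: ",
                 paste(unique(x$site_class[bad]), collapse = ", "),
                 class = "mmclone_format_error")
  if (any(!is.finite(x$purity) | x$purity <= 0 | x$purity > 1))
    stop_mmclone("sample sheet: purity must be in (0, 1]",
                 class = "mmclone_format_error")
  if (any(!is.finite(x$timepoint) | x$timepoint < 0))
    stop_mmclone("sample sheet: timepoint must be a nonnegative ordinal",
                 class = "mmclone_format_error")
  if (anyDuplicated(x$sample_id))
    stop_mmclone("sample sheet: duplicated sample_id",
                 class = "mmclone_format_error")
  x[c("sample_id", "patient_id", "site_class", "anatomical_label",
      "timepoint", "purity")]
}

#' Immunoglobulin-locus exclusion intervals
#'
#' Reads a table of genomic intervals (columns \code{chrom start end
#' locus}) used to flag and exclude variants falling in the
#' immunoglobulin loci. The packaged default covers IGH (chr14), IGK
#' (chr2) and IGL (chr22) on GRCh37 and can be replaced by any
#' user-supplied file in the same format.
#'
#' @param path Path to an interval table; defaults to the packaged
#'   GRCh37 file.
#' @return data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{locus}.
#' @export
read_ig_loci <- function(path = system.file("extdata",
                                            "ig_loci_grch37.tsv",
                                            package = "mmclone")) {
  x <- read_tsv_checked(path, c("chrom", "start", "end"), "ig loci")
  x$chrom <- sub("^chr", "", as.character(x$chrom))
  x
}

in_intervals <- function(chrom, pos, intervals) {
  chrom <- sub("^chr", "", as.character(chrom))
  out <- logical(length(chrom))
  for (i in seq_len(nrow(intervals))) {
    out <- out | (chrom == intervals$chrom[i] &
                    pos >= intervals$start[i] & pos <= intervals$end[i])
  }
  out
}

#' Read a per-patient somatic mutation table
#'
#' Parses the tab-separated mutation dialect of \link{io-formats} and
#' reconciles its per-sample columns against a sample sheet. Rows with
#' malformed coordinates or alleles, or with \code{alt > depth} in any
#' sample, are rejected with a row-level diagnostic rather than aborting
#' the run.
#'
#' @param path Path to the mutation table.
#' @param sample_sheet data.frame from [read_sample_sheet()] (or a
#'   subset covering one patient).
#' @param ig_loci Interval table from [read_ig_loci()] used to set the
#'   \code{in_ig_locus} flag; \code{NULL} disables flagging.
#' @return A list with elements
#'   \describe{
#'     \item{variants}{one row per retained variant: \code{variant_id},
#'       \code{chrom}, \code{pos}, \code{ref}, \code{alt}, \code{gene},
#'       \code{context96}, \code{in_ig_locus}.}
#'     \item{observations}{long table, one row per (variant, sample):
#'       \code{variant_id}, \code{sample_id}, \code{alt_reads},
#'       \code{depth}, \code{qc_pass}.}
#'     \item{rejected}{diagnostics for dropped rows: \code{row},
#'       \code{variant_id}, \code{reason}.}
#'   }
#' @export
read_mutation_table <- function(path, sample_sheet,
                                ig_loci = read_ig_loci()) {
  x <- read_tsv_checked(path, c("variant_id", "chrom", "pos", "ref",
                                "alt", "gene"), "mutation table")
  cn <- names(x)
  alt_cols <- grep(":alt$", cn, value = TRUE)
  dep_cols <- grep(":depth$", cn, value = TRUE)
  tab_samples <- sub(":alt$", "", alt_cols)
  if (!setequal(tab_samples, sub(":depth$", "", dep_cols)))
    stop_mmclone("mutation table: unpaired <sample>:alt/<sample>:depth ",
                 "columns", class = "mmclone_format_error")
  sheet_samples <- sample_sheet$sample_id
  if (!setequal(tab_samples, sheet_samples))
    stop_mmclone(
      "mutation table/sample sheet mismatch; table-only: [",
      paste(setdiff(tab_samples, sheet_samples), collapse = ", "),
      "], sheet-only: [",
      paste(setdiff(sheet_samples, tab_samples), collapse = ", "), "]",
      class = "mmclone_reconcile_error")
  samples <- sheet_samples

  pos <- suppressWarnings(as.numeric(x$pos))
  reason <- rep(NA_character_, nrow(x))
  bad_pos <- !is.finite(pos) | pos < 1 | pos != floor(pos)
  reason[bad_pos] <- "malformed position"
  bad_allele <- is.na(reason) &
    (!(toupper(x$ref) %in% c("A", "C", "G", "T")) |
       !(toupper(x$alt) %in% c("A", "C", "G", "T")) |
       toupper(x$ref) == toupper(x$alt))
  reason[bad_allele] <- "malformed ref/alt"
  for (s in samples) {
    a <- suppressWarnings(as.numeric(x[[paste0(s, ":alt")]]))
    d <- suppressWarnings(as.numeric(x[[paste0(s, ":depth")]]))
    bad <- is.na(reason) & (!is.finite(a) | !is.finite(d) | a < 0 |
                              d < 0 | a > d)
    reason[bad] <- paste0("invalid read counts in sample ", s)
  }
  dup <- duplicated(x$variant_id)
  reason[is.na(reason) & dup] <- "duplicated variant_id"

  keep <- is.na(reason)
  rejected <- data.frame(row = which(!keep),
                         variant_id = x$variant_id[!keep],
                         reason = reason[!keep],
                         stringsAsFactors = FALSE)

  v <- x[keep, , drop = FALSE]
  ctx <- if ("context96" %in% names(v)) {
    as.integer(v$context96)
  } else rep(NA_integer_, nrow(v))
  variants <- data.frame(
    variant_id = v$variant_id, chrom = as.character(v$chrom),
    pos = as.integer(pos[keep]), ref = toupper(v$ref),
    alt = toupper(v$alt), gene = as.character(v$gene),
    context96 = ctx,
    in_ig_locus = if (is.null(ig_loci)) FALSE else
      in_intervals(v$chrom, pos[keep], ig_loci),
    stringsAsFactors = FALSE)

  obs <- do.call(rbind, lapply(samples, function(s) {
    qc_col <- paste0(s, ":qc")
    data.frame(
      variant_id = variants$variant_id, sample_id = s,
      alt_reads = as.integer(v[[paste0(s, ":alt")]]),
      depth = as.integer(v[[paste0(s, ":depth")]]),
      qc_pass = if (qc_col %in% names(v)) as.logical(v[[qc_col]]) else TRUE,
      stringsAsFactors = FALSE)
  }))
  rownames(obs) <- NULL
  list(variants = variants, observations = obs, rejected = rejected)
}

#' Write a mutation table
#'
#' Serializes variants and observations back to the tab-separated
#' mutation dialect read by [read_mutation_table()]; parsing the output
#' reproduces every retained field.
#'
#' @param variants,observations As returned by [read_mutation_table()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_mutation_table <- function(variants, observations, path) {
  out <- variants[c("variant_id", "chrom", "pos", "ref", "alt", "gene",
                    "context96")]
  for (s in unique(observations$sample_id)) {
    o <- observations[observations$sample_id == s, ]
    i <- match(out$variant_id, o$variant_id)
    out[[paste0(s, ":alt")]] <- o$alt_reads[i]
    out[[paste0(s, ":depth")]] <- o$depth[i]
    out[[paste0(s, ":qc")]] <- o$qc_pass[i]
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SEG-like copy-number segment table
#'
#' @param path Path to a tab-separated file with columns \code{sample
#'   chrom start end total_cn minor_cn} (1-based inclusive coordinates).
#' @return data.frame of segments sorted by (sample, chrom, start) with
#'   an added \code{length_bp} column. Overlapping segments within a
#'   sample trigger a warning.
#' @export
read_segments <- function(path) {
  x <- read_tsv_checked(path, c("sample", "chrom", "start", "end",
                                "total_cn", "minor_cn"), "segments")
  x$chrom <- as.character(x$chrom)
  for (col in c("start", "end", "total_cn", "minor_cn"))
    x[[col]] <- as.integer(x[[col]])
  if (any(x$start > x$end))
    stop_mmclone("segments: start > end", class = "mmclone_format_error")
  if (any(x$total_cn < 0 | x$minor_cn < 0 | x$minor_cn > x$total_cn))
    stop_mmclone("segments: need 0 <= minor_cn <= total_cn",
                 class = "mmclone_format_error")
  x <- x[order(x$sample, x$chrom, x$start), , drop = FALSE]
  rownames(x) <- NULL
  x$length_bp <- x$end - x$start + 1L
  by_sc <- split(seq_len(nrow(x)), paste(x$sample, x$chrom))
  for (idx in by_sc) {
    if (length(idx) > 1 &&
        any(x$start[idx][-1] <= x$end[idx][-length(idx)]))
      warning("overlapping segments within sample ", x$sample[idx[1]],
              " on chromosome ", x$chrom[idx[1]])
  }
  x
}

#' Read a COSMIC-style 96-context signature catalog
#'
#' Rows are reordered to the canonical 96-context ordering (see
#' [sbs96_contexts()]) regardless of input order, and each signature
#' column is renormalized to sum to exactly 1.
#'
#' @param path Path to a tab-separated catalog with a \code{Type} column
#'   and one column per signature.
#' @return An object of class \code{sig_catalog}: list with
#'   \code{names} (signature ids) and \code{profiles} (96 x K matrix,
#'   rownames the context strings, each column summing to 1).
#' @export
read_signature_catalog <- function(path) {
  x <- read_tsv_checked(path, "Type", "signature catalog")
  if (nrow(x) != 96)
    stop_mmclone("signature catalog: expected 96 context rows, got ",
                 nrow(x), class = "mmclone_format_error")
  idx <- context96_from_type(x$Type)
  if (anyNA(idx) || anyDuplicated(idx))
    stop_mmclone("signature catalog: Type column must contain each of ",
                 "the 96 contexts exactly once",
                 class = "mmclone_format_error")
  prof <- as.matrix(x[order(idx), setdiff(names(x), "Type"),
                      drop = FALSE])
  storage.mode(prof) <- "double"
  if (any(!is.finite(prof)) || any(prof < 0))
    stop_mmclone("signature catalog: entries must be finite and >= 0",
                 class = "mmclone_format_error")
  sig_catalog(prof, colnames(prof))
}

#' Construct a signature catalog from a profile matrix
#'
#' @param profiles 96 x K numeric matrix of context probabilities
#'   (columns are renormalized to sum to 1).
#' @param names Signature ids; defaults to the column names.
#' @return A \code{sig_catalog} object.
#' @export
sig_catalog <- function(profiles, names = colnames(profiles)) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) != 96)
    stop_mmclone("profiles must have 96 rows",
                 class = "mmclone_format_error")
  cs <- colSums(profiles)
  if (any(cs <= 0))
    stop_mmclone("signature column sums must be positive",
                 class = "mmclone_format_error")
  profiles <- sweep(profiles, 2, cs, "/")
  rownames(profiles) <- sbs96_contexts()
  colnames(profiles) <- names
  structure(list(names = names, profiles = profiles),
            class = "sig_catalog")
}

#' @export
print.sig_catalog <- function(x, ...) {
  cat("<sig_catalog>", length(x$names), "signatures over 96 contexts:",
      paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

#' Read a clinical table
#'
#' @param path Tab-separated file with columns \code{patient_id},
#'   \code{pet_fl_count} (PET-positive focal lesions at baseline),
#'   \code{best_response} (CR/VGPR/PR/SD/PD) and optionally
#'   \code{gep70_score}.
#' @return data.frame with a derived \code{gep70_risk} column
#'   (\code{"high"} iff score >= 0.66; \code{NA} when score missing).
#' @export
read_clinical_table <- function(path) {
  x <- read_tsv_checked(path, c("patient_id", "pet_fl_count",
                                "best_response"), "clinical table")
  x$pet_fl_count <- as.integer(x$pet_fl_count)
  if (any(!is.na(x$pet_fl_count) & x$pet_fl_count < 0))
    stop_mmclone("clinical table: pet_fl_count must be >= 0",
                 class = "mmclone_format_error")
  bad <- !is.na(x$best_response) & !(x$best_response %in% RESPONSES)
  if (any(bad))
    stop_mmclone("clinical table: unknown best_response: ",
                 paste(unique(x$best_response[bad]), collapse = ", "),
                 class = "mmclone_format_error")
  if (is.null(x$gep70_score)) x$gep70_score <- NA_real_
  x$gep70_risk <- ifelse(is.na(x$gep70_score), NA_character_,
                         ifelse(x$gep70_score >= 0.66, "high", "low"))
  x
}
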