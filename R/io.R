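#' Write a cell-by-feature count matrix as a 10x-style MTX triplet
#'
#' Writes `matrix.mtx`, `barcodes.tsv` and `features.tsv` into `dir`.
#' `features.tsv` carries three columns: feature id, feature name (identical
#' to the id here) and a feature class, a conservative extension of the 10x
#' dialect used to mark `"Gene Expression"`, `"Transgene"` and `"Mito"`
#' features.
#'
#' @param counts A features-by-cells [Matrix::dgCMatrix-class] with row and
#'   column names.
#' @param dir Output directory (created if missing).
#' @param feature_class Character vector of feature classes, one per row of
#'   `counts`; defaults to `"Gene Expression"` everywhere.
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(counts, dir, feature_class = NULL) {
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)))
  if (is.null(feature_class)) feature_class <- rep("Gene Expression", nrow(counts))
  if (length(feature_class) != nrow(counts))
    stop_ct("feature_class must have one entry per feature")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"), file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(
    data.frame(id = rownames(counts), name = rownames(counts), class = feature_class),
    file.path(dir, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(dir)
}

#' Read a 10x-style MTX triplet
#'
#' Accepts plain or gzipped `matrix.mtx`, `barcodes.tsv`, `features.tsv`.
#' A two-column features file is accepted (class defaults to
#' `"Gene Expression"`); mitochondrial features may alternatively be
#' recognised downstream by an `MT-` name prefix.
#'
#' @param dir Directory holding the triplet.
#' @return A list with `counts` (features-by-cells dgCMatrix) and
#'   `feature_class` (character vector aligned with the rows).
#' @export
read_counts_mtx <- function(dir) {
  pick <- function(base) {
    for (f in file.path(dir, c(base, paste0(base, ".gz")))) if (file.exists(f)) return(f)
    stop_ct("missing ", base, " in ", dir)
  }
  mf <- pick("matrix.mtx")
  m <- if (grepl("\\.gz$", mf)) Matrix::readMM(gzfile(mf)) else Matrix::readMM(mf)
  barcodes <- readLines(pick("barcodes.tsv"))
  feats <- utils::read.table(pick("features.tsv"), sep = "\t", header = FALSE,
                             colClasses = "character", quote = "")
  if (nrow(feats) != nrow(m) || length(barcodes) != ncol(m))
    stop_ct("dimension mismatch between matrix (", nrow(m), "x", ncol(m),
            ") and features/barcodes files (", nrow(feats), "/", length(barcodes), ")")
  counts <- methods::as(m, "CsparseMatrix")
  rownames(counts) <- feats[[1L]]
  colnames(counts) <- barcodes
  cls <- if (ncol(feats) >= 3L) feats[[3L]] else rep("Gene Expression", nrow(feats))
  list(counts = counts, feature_class = cls)
}

#' Read a pair of lock-step FASTQ files
#'
#' @param r1,r2 Paths to the R1 and R2 FASTQ files (plain or gzipped).
#' @return A data.frame with `id`, `seq1`, `seq2`.
#' @export
read_fastq_pair <- function(r1, r2) {
  s1 <- Biostrings::readDNAStringSet(r1, format = "fastq")
  s2 <- Biostrings::readDNAStringSet(r2, format = "fastq")
  if (length(s1) != length(s2))
    stop_ct("unpaired FASTQ: R1 has ", length(s1), " reads, R2 has ", length(s2),
            "; first unmatched read index ", min(length(s1), length(s2)) + 1L)
  id1 <- sub("[/ ].*$", "", names(s1))
  id2 <- sub("[/ ].*$", "", names(s2))
  bad <- which(id1 != id2)
  if (length(bad))
    stop_ct("FASTQ pair out of order at read index ", bad[1L])
  data.frame(id = id1, seq1 = as.character(s1), seq2 = as.character(s2))
}

# write one FASTQ file (constant qualities; the pipeline never uses them)
write_fastq <- function(ids, seqs, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  qual <- strrep("I", nchar(seqs))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), con)
  invisible(path)
}

#' Read a per-cell metadata table
#'
#' Tab-delimited with a header; lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return A data.frame.
#' @export
read_metadata_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    quote = "", stringsAsFactors = FALSE)
}

#' Write an output table with a provenance header comment
#'
#' Every pipeline output table declares the producing stage and its
#' parameters on a leading `#` comment line.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @param stage Stage name.
#' @param params Named list of parameters recorded in the header.
#' @return `path`, invisibly.
#' @export
write_stage_tsv <- function(df, path, stage, params = list()) {
  hdr <- paste0("# convtrace stage=", stage,
                if (length(params))
                  paste0(" ", paste(names(params), unlist(params), sep = "=", collapse = " "))
                else "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
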