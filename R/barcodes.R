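# all 1-substitution variants of a flank, for optional mismatch-tolerant
# motif matching
flank_variants <- function(flank) {
  bases <- c("A", "C", "G", "T")
  s <- strsplit(flank, "", fixed = TRUE)[[1L]]
  out <- character(0)
  for (i in seq_along(s)) for (b in setdiff(bases, s[i])) {
    v <- s; v[i] <- b
    out <- c(out, paste(v, collapse = ""))
  }
  out
}

#' Extract lineage-barcode records from a FASTQ pair
#'
#' Scans R2 for the barcode cassette motif (5' flank, 20 nt of `[ACGT]`,
#' 3' flank; first match wins) and emits one record per matching read:
#' read id, the 16-nt cell barcode (R1 positions 1-16), the 12-nt UMI (R1
#' positions 17-28), the 20-nt viral barcode between the flanks and the
#' 12-nt library ID immediately after the 3' flank (empty, and counted,
#' when R2 is too short). Non-matching reads are skipped and counted.
#'
#' @param fastq_r1,fastq_r2 Paths to the paired FASTQ files.
#' @param flank5,flank3 Static flanks (defaults `GTCGTGA` / `CTCGAC`).
#' @param barcode_len Barcode length (default 20).
#' @param max_flank_mismatch 0 for exact flanks (default) or 1 to tolerate
#'   one substitution per flank.
#' @return Object of class `barcode_records`: list with `records`
#'   (data.frame), `n_total`, `n_skipped`, `n_short_library_id`.
#' @export
extract_barcodes <- function(fastq_r1, fastq_r2, flank5 = "GTCGTGA",
                             flank3 = "CTCGAC", barcode_len = 20L,
                             max_flank_mismatch = 0L) {
  reads <- read_fastq_pair(fastq_r1, fastq_r2)
  f5 <- if (max_flank_mismatch >= 1L)
    paste0("(?:", paste(c(flank5, flank_variants(flank5)), collapse = "|"), ")")
  else flank5
  f3 <- if (max_flank_mismatch >= 1L)
    paste0("(?:", paste(c(flank3, flank_variants(flank3)), collapse = "|"), ")")
  else flank3
  pat <- paste0(f5, "([ACGT]{", barcode_len, "})", f3)
  m <- regexpr(pat, reads$seq2, perl = TRUE)
  hit <- m != -1L
  start <- m[hit]
  # capture-group positions for the viral barcode
  cap_start <- attr(m, "capture.start")[hit, 1L]
  vb <- substr(reads$seq2[hit], cap_start, cap_start + barcode_len - 1L)
  lib_start <- start + attr(m, "match.length")[hit]
  lib <- substr(reads$seq2[hit], lib_start, lib_start + 11L)
  short <- nchar(lib) < 12L
  lib[short] <- ""
  records <- data.frame(
    read_id = reads$id[hit],
    cell_barcode = substr(reads$seq1[hit], 1L, 16L),
    umi = substr(reads$seq1[hit], 17L, 28L),
    viral_barcode = vb,
    library_id = lib
  )
  structure(list(records = records, n_total = nrow(reads),
                 n_skipped = sum(!hit), n_short_library_id = sum(short)),
            class = "barcode_records")
}

#' @export
print.barcode_records <- function(x, ...) {
  cat("barcode_records:", nrow(x$records), "records from", x$n_total, "reads (",
      x$n_skipped, "without motif,", x$n_short_library_id, "short library IDs)\n")
  invisible(x)
}

#' Count distinct barcode UMIs per cell
#'
#' Records are deduplicated by (cell barcode, viral barcode, UMI) before
#' counting, so counts are distinct molecules, not reads.
#'
#' @param records A `barcode_records` object or its `records` data.frame.
#' @return Long-form data.frame (`cell_barcode`, `viral_barcode`,
#'   `umi_count`).
#' @export
count_barcode_umis <- function(records) {
  df <- if (inherits(records, "barcode_records")) records$records else records
  key <- unique(df[, c("cell_barcode", "viral_barcode", "umi")])
  agg <- stats::aggregate(list(umi_count = key$umi),
                          by = key[, c("cell_barcode", "viral_barcode")], FUN = length)
  agg[order(agg$cell_barcode, -agg$umi_count, agg$viral_barcode), ]
}

# one directional pass within one cell: descending count (ties
# lexicographic); a barcode merges into the already-kept barcode of
# highest original count that is strictly larger and within max_dist
collapse_pass <- function(bc, cnt, max_dist) {
  ord <- order(-cnt, bc)
  bc <- bc[ord]; cnt <- cnt[ord]
  to <- rep(NA_integer_, length(bc))
  kept <- integer(0)
  for (i in seq_along(bc)) {
    tgt <- NA_integer_
    for (k in kept) {
      if (cnt[k] > cnt[i] &&
          utils::adist(bc[k], bc[i])[1L, 1L] <= max_dist) { tgt <- k; break }
    }
    if (is.na(tgt)) kept <- c(kept, i) else to[i] <- tgt
  }
  list(barcode = bc, count = cnt, merged_into = to)
}

#' Error-correct viral barcodes by directional edit-distance collapse
#'
#' Within each cell independently, a barcode is merged into a barcode with
#' strictly greater count when their Levenshtein distance is at most
#' `max_dist`; candidates are processed in descending-count order with
#' lexicographic tie-break, merged counts add, and passes repeat until no
#' further merge is possible (so the operation is idempotent and matches a
#' transitive-closure formulation of the same directional rule). Barcodes
#' in different cells are never compared.
#'
#' @param mat Long-form matrix from [count_barcode_umis()].
#' @param max_dist Maximum edit distance to collapse (default 1).
#' @return List with `matrix` (corrected long form) and `log` (data.frame
#'   of every merge: cell, from, to, count moved).
#' @export
correct_barcodes <- function(mat, max_dist = 1L) {
  pieces <- split(mat, mat$cell_barcode)
  logs <- list()
  out <- lapply(names(pieces), function(cell) {
    d <- pieces[[cell]]
    bc <- d$viral_barcode
    cnt <- as.numeric(d$umi_count)
    repeat {
      res <- collapse_pass(bc, cnt, max_dist)
      if (all(is.na(res$merged_into))) { bc <- res$barcode; cnt <- res$count; break }
      merged <- which(!is.na(res$merged_into))
      logs[[length(logs) + 1L]] <<- data.frame(
        cell_barcode = cell, from = res$barcode[merged],
        to = res$barcode[res$merged_into[merged]], count = res$count[merged])
      newc <- res$count
      for (i in merged) newc[res$merged_into[i]] <- newc[res$merged_into[i]] + res$count[i]
      keep <- setdiff(seq_along(res$barcode), merged)
      bc <- res$barcode[keep]; cnt <- newc[keep]
    }
    data.frame(cell_barcode = cell, viral_barcode = bc, umi_count = cnt)
  })
  corrected <- do.call(rbind, out)
  corrected <- corrected[order(corrected$cell_barcode, -corrected$umi_count,
                               corrected$viral_barcode), ]
  rownames(corrected) <- NULL
  log <- if (length(logs)) do.call(rbind, logs) else
    data.frame(cell_barcode = character(0), from = character(0),
               to = character(0), count = numeric(0))
  list(matrix = corrected, log = log)
}

#' Filter the cell-barcode matrix against whitelist and retained cells
#'
#' @param mat Long-form cell/barcode matrix.
#' @param whitelist Character vector (or path to a TSV) of accepted cell
#'   barcodes.
#' @param retained_cells Optional character vector of QC-passing cells.
#' @return List with `matrix` (filtered) and `report` (per-rule removal
#'   counts). Errors when nothing survives.
#' @export
filter_whitelist <- function(mat, whitelist, retained_cells = NULL) {
  if (length(whitelist) == 1L && file.exists(whitelist))
    whitelist <- readLines(whitelist)
  in_wl <- mat$cell_barcode %in% whitelist
  in_ret <- if (is.null(retained_cells)) rep(TRUE, nrow(mat)) else
    mat$cell_barcode %in% retained_cells
  keep <- in_wl & in_ret
  if (!any(keep)) stop_ct("no cell barcode survives whitelist/retained-cell filtering")
  list(matrix = mat[keep, , drop = FALSE],
       report = list(n_input = nrow(mat),
                     n_removed_whitelist = sum(!in_wl),
                     n_removed_not_retained = sum(in_wl & !in_ret),
                     n_retained = sum(keep)))
}

#' Assign each cell to its top barcode and build the clone table
#'
#' A cell is assigned its highest-UMI barcode when that count is at least
#' `min_umi` and its share of the cell's barcode UMIs is at least
#' `purity`; a tie for the top barcode leaves the cell unassigned with a
#' flag. Cells sharing an assigned barcode form a clone.
#'
#' @param mat Corrected, filtered long-form matrix.
#' @param metadata Optional data.frame with `cell`, `timepoint` and
#'   optionally `cluster` columns, joined into the clone table.
#' @param min_umi Minimum UMIs of the top barcode (default 1).
#' @param purity Minimum top-barcode share of the cell total (default 0).
#' @return List with `assignments` (per cell: top barcode, counts,
#'   assigned flag, reason) and `clone_table` (one row per assigned cell:
#'   clone id = barcode, cell, timepoint/cluster when available).
#' @export
assign_clones <- function(mat, metadata = NULL, min_umi = 1L, purity = 0) {
  per_cell <- split(mat, mat$cell_barcode)
  rows <- lapply(per_cell, function(d) {
    tot <- sum(d$umi_count)
    top <- max(d$umi_count)
    cand <- d$viral_barcode[d$umi_count == top]
    if (length(cand) > 1L)
      return(data.frame(cell = d$cell_barcode[1L], barcode = NA_character_,
                        umi_top = top, umi_total = tot, assigned = FALSE,
                        reason = "tie"))
    if (top < min_umi)
      return(data.frame(cell = d$cell_barcode[1L], barcode = NA_character_,
                        umi_top = top, umi_total = tot, assigned = FALSE,
                        reason = "min_umi"))
    if (top / tot < purity)
      return(data.frame(cell = d$cell_barcode[1L], barcode = NA_character_,
                        umi_top = top, umi_total = tot, assigned = FALSE,
                        reason = "purity"))
    data.frame(cell = d$cell_barcode[1L], barcode = cand, umi_top = top,
               umi_total = tot, assigned = TRUE, reason = "")
  })
  assignments <- do.call(rbind, rows)
  rownames(assignments) <- NULL
  clone <- assignments[assignments$assigned, c("cell", "barcode")]
  names(clone) <- c("cell", "clone_id")
  if (!is.null(metadata)) {
    j <- match(clone$cell, metadata$cell)
    clone$timepoint <- metadata$timepoint[j]
    if ("cluster" %in% names(metadata)) clone$cluster <- metadata$cluster[j]
  }
  list(assignments = assignments, clone_table = clone)
}

#' Barcode detection rate, overall and per cell type
#'
#' @param detected_cells Cells with an assigned barcode.
#' @param all_cells All analysed cells.
#' @param annotation Optional named per-cell annotation for a per-type
#'   breakdown.
#' @param conf_level Binomial CI level.
#' @return data.frame with detection fraction and exact binomial CI per
#'   group (`overall` first); empty groups give NA.
#' @export
barcode_detection_rate <- function(detected_cells, all_cells, annotation = NULL,
                                   conf_level = 0.95) {
  one <- function(name, cells) {
    n <- length(cells)
    if (n == 0L)
      return(data.frame(group = name, n = 0L, n_detected = 0L,
                        fraction = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_))
    k <- sum(cells %in% detected_cells)
    ci <- stats::binom.test(k, n, conf.level = conf_level)$conf.int
    data.frame(group = name, n = n, n_detected = k, fraction = k / n,
               ci_lo = ci[1L], ci_hi = ci[2L])
  }
  out <- one("overall", all_cells)
  if (!is.null(annotation)) {
    ann <- annotation[all_cells]
    for (g in sort(unique(stats::na.omit(as.character(ann)))))
      out <- rbind(out, one(g, all_cells[!is.na(ann) & ann == g]))
  }
  rownames(out) <- NULL
  out
}

#' Summarise clones: size, cell-type breadth, window coverage
#'
#' @param clone_table Clone table from [assign_clones()] with `timepoint`
#'   (and optionally `cluster`) columns.
#' @param d0_label Label of the pre-conversion timepoint (default `"D0"`).
#' @return List with `clones` (per clone: size, distinct cell types,
#'   presence before/after conversion) and `composition` (long per-clone
#'   timepoint counts).
#' @export
clone_summary <- function(clone_table, d0_label = "D0") {
  if (!nrow(clone_table)) stop_ct("empty clone table")
  has_cl <- "cluster" %in% names(clone_table)
  per <- split(clone_table, clone_table$clone_id)
  clones <- do.call(rbind, lapply(per, function(d) data.frame(
    clone_id = d$clone_id[1L],
    size = nrow(d),
    n_cell_types = if (has_cl) length(unique(d$cluster)) else NA_integer_,
    has_d0 = any(d$timepoint == d0_label),
    has_post = any(d$timepoint != d0_label)
  )))
  clones$before_and_after <- clones$has_d0 & clones$has_post
  rownames(clones) <- NULL
  comp <- as.data.frame(table(clone_id = clone_table$clone_id,
                              timepoint = clone_table$timepoint),
                        responseName = "n")
  list(clones = clones[order(-clones$size, clones$clone_id), ],
       composition = comp[comp$n > 0L, ])
}
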