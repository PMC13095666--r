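#' Filter guide reads by mapping quality
#'
#' Retains aligned guide-RNA read records whose mapping quality passes the
#' threshold. The boundary is inclusive: a read with `mapq == mapq_min`
#' is kept. Record order is preserved and the input is not modified.
#'
#' @param records Data frame of guide read records with at least the columns
#'   `cell_barcode`, `guide_id`, `mapq` and `read_id`; an optional `umi`
#'   column is carried through.
#' @param mapq_min Minimum mapping quality to retain (default 30).
#' @return The subset of `records` with `mapq >= mapq_min`.
#' @export
#' @examples
#' reads <- data.frame(cell_barcode = "A", guide_id = "g1",
#'                     mapq = c(30, 29), read_id = c("r1", "r2"))
#' filter_guide_reads(reads)
filter_guide_reads <- function(records, mapq_min = 30) {
  if (!is.numeric(mapq_min) || length(mapq_min) != 1L || mapq_min < 0) {
    .stopf("'mapq_min' must be a single nonnegative number")
  }
  .check_guide_records(records)
  records[records$mapq >= mapq_min, , drop = FALSE]
}

#' @keywords internal
.check_guide_records <- function(records) {
  need <- c("cell_barcode", "guide_id", "mapq", "read_id")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    .stopf("guide read table is missing column(s): %s",
           paste(miss, collapse = ", "))
  }
  if (nrow(records) && any(!is.finite(records$mapq))) {
    .stopf("non-finite MAPQ values in guide read table")
  }
  if (nrow(records) && any(!nzchar(records$cell_barcode))) {
    .stopf("empty cell barcodes in guide read table")
  }
  invisible(records)
}

#' Count deduplicated guide reads per cell
#'
#' Tallies supporting reads for every (cell barcode, guide) combination.
#' With `dedup_by_umi = TRUE`, PCR duplicates are collapsed by counting
#' unique (cell, UMI, guide) triples; otherwise unique `read_id`s are
#' counted. Records are assumed to be MAPQ-filtered already.
#'
#' @param records Data frame of guide read records (see
#'   [filter_guide_reads()]).
#' @param dedup_by_umi Collapse reads sharing a UMI within a cell/guide
#'   (default `FALSE`). Requires a complete `umi` column.
#' @return Data frame with columns `cell_barcode`, `guide_id`, `n`.
#' @export
count_guides_per_cell <- function(records, dedup_by_umi = FALSE) {
  .check_guide_records(records)
  if (nrow(records) == 0L) {
    return(data.frame(cell_barcode = character(), guide_id = character(),
                      n = integer(), stringsAsFactors = FALSE))
  }
  if (dedup_by_umi) {
    if (is.null(records$umi) || anyNA(records$umi) ||
        any(!nzchar(records$umi))) {
      bad <- if (is.null(records$umi)) "all records" else {
        idx <- which(is.na(records$umi) | !nzchar(records$umi))[1L]
        sprintf("record %d (read_id '%s')", idx, records$read_id[idx])
      }
      .stopf("UMI deduplication requested but UMI missing for %s", bad)
    }
    key <- paste(records$cell_barcode, records$guide_id, records$umi,
                 sep = "\r")
  } else {
    key <- paste(records$cell_barcode, records$guide_id, records$read_id,
                 sep = "\r")
  }
  uniq <- records[!duplicated(key), c("cell_barcode", "guide_id")]
  agg <- stats::aggregate(list(n = rep.int(1L, nrow(uniq))),
                          by = uniq[c("cell_barcode", "guide_id")],
                          FUN = sum)
  agg <- agg[order(agg$cell_barcode, agg$guide_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg$n <- as.integer(agg$n)
  agg
}

#' Assign a unique guide RNA to each cell
#'
#' Applies the screening assignment rule: a cell is `assigned` to its most
#' abundant guide when it has at least `min_reads` deduplicated guide reads
#' and the most abundant guide accounts for strictly more than `dominance`
#' of them; cells with enough reads but no strictly dominant guide are
#' `ambiguous` (a tie for the top guide is always ambiguous); cells with
#' fewer than `min_reads` reads are `unassigned`.
#'
#' @param counts Data frame from [count_guides_per_cell()] with columns
#'   `cell_barcode`, `guide_id`, `n`.
#' @param min_reads Minimum deduplicated reads for assignment (default 2).
#' @param dominance Strict read-fraction threshold for the top guide
#'   (default 2/3, i.e. the >2:3 rule).
#' @param cells Optional character vector of all cell barcodes; barcodes
#'   with no counted reads are reported as `unassigned` with
#'   `total_reads = 0`.
#' @return Data frame with columns `cell_barcode`, `status`, `guide_id`,
#'   `top_reads`, `total_reads`.
#' @export
#' @examples
#' cnt <- data.frame(cell_barcode = c("A", "A", "B"),
#'                   guide_id = c("g1", "g2", "g1"), n = c(3L, 1L, 2L))
#' assign_guides(cnt)
assign_guides <- function(counts, min_reads = 2, dominance = 2 / 3,
                          cells = NULL) {
  .check_fraction(dominance, "dominance", open_lower = TRUE,
                  open_upper = TRUE)
  min_reads <- .check_count(min_reads, "min_reads", min = 0)
  if (nrow(counts) && any(counts$n < 0)) {
    .stopf("negative guide read counts")
  }
  split_idx <- split(seq_len(nrow(counts)), counts$cell_barcode)
  res <- lapply(names(split_idx), function(cb) {
    idx <- split_idx[[cb]]
    n <- counts$n[idx]
    total <- sum(n)
    top_i <- which.max(n)
    top <- n[top_i]
    tie <- sum(n == top) > 1L
    if (total < min_reads) {
      status <- "unassigned"; gid <- NA_character_
    } else if (!tie && top / total > dominance) {
      status <- "assigned"; gid <- counts$guide_id[idx][top_i]
    } else {
      status <- "ambiguous"; gid <- NA_character_
    }
    data.frame(cell_barcode = cb, status = status, guide_id = gid,
               top_reads = as.integer(top), total_reads = as.integer(total),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(cell_barcode = character(), status = character(),
                      guide_id = character(), top_reads = integer(),
                      total_reads = integer(), stringsAsFactors = FALSE)
  }
  if (!is.null(cells)) {
    absent <- setdiff(cells, out$cell_barcode)
    if (length(absent)) {
      out <- rbind(out, data.frame(
        cell_barcode = absent, status = "unassigned",
        guide_id = NA_character_, top_reads = 0L, total_reads = 0L,
        stringsAsFactors = FALSE))
    }
    out <- out[match(sort(unique(c(cells, out$cell_barcode))),
                     out$cell_barcode), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Summarize guide assignments
#'
#' Reports counts and percentages of cells per assignment status and the
#' per-guide group sizes. Percentages are `100 * count / n_cells_total`,
#' rounded to one decimal.
#'
#' @param assignments Data frame from [assign_guides()].
#' @param n_cells_total Total number of cells in the experiment; must be at
#'   least the number of assignment rows.
#' @return List with elements `status` (data frame of count and percent per
#'   status), `per_guide` (data frame of assigned-cell counts per guide)
#'   and `guide_group_size` (list with `mean` and `sd` across guides).
#' @export
summarize_assignment <- function(assignments, n_cells_total) {
  if (!is.numeric(n_cells_total) || length(n_cells_total) != 1L ||
      n_cells_total <= 0) {
    .stopf("'n_cells_total' must be a positive number")
  }
  if (n_cells_total < nrow(assignments)) {
    .stopf("'n_cells_total' (%d) is smaller than the number of assignments (%d)",
           n_cells_total, nrow(assignments))
  }
  lv <- c("assigned", "ambiguous", "unassigned")
  tab <- table(factor(assignments$status, levels = lv))
  status <- data.frame(status = lv, count = as.integer(tab),
                       percent = round(100 * as.integer(tab) / n_cells_total,
                                       1),
                       stringsAsFactors = FALSE)
  asg <- assignments[assignments$status == "assigned", , drop = FALSE]
  per_guide <- if (nrow(asg)) {
    t2 <- table(asg$guide_id)
    data.frame(guide_id = names(t2), n_cells = as.integer(t2),
               stringsAsFactors = FALSE)
  } else {
    data.frame(guide_id = character(), n_cells = integer(),
               stringsAsFactors = FALSE)
  }
  list(status = status,
       per_guide = per_guide,
       guide_group_size = list(
         mean = if (nrow(per_guide)) mean(per_guide$n_cells) else NA_real_,
         sd = if (nrow(per_guide) > 1) stats::sd(per_guide$n_cells)
              else NA_real_))
}
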