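# Readers and writers for every file the pipeline touches. All tables are
# plain TSV with headers; genomic intervals are BED3+ (0-based, half-open)
# and are stored internally in exactly that convention. Interval arithmetic
# elsewhere converts once to IRanges (1-based, closed) and back.

INTERVAL_KINDS <- c("gene", "css_window", "ecopeak", "qtl")

.count_cols <- c("gene_id", "tissue", "timepoint", "replicate",
                 "marine_count", "freshwater_count")
.site_cols <- c("chrom", "pos", "gene_id", "marine_count", "freshwater_count")

.check_counts <- function(vals, col, path) {
  bad <- which(is.na(vals) | vals < 0 | vals != floor(vals))
  if (length(bad)) {
    stop(sprintf("%s: column '%s' must hold non-negative integers (first bad data line: %d)",
                 path, col, bad[1]))
  }
}

#' Read a gene-level allelic count table
#'
#' Tab-separated with header columns `gene_id`, `tissue`, `timepoint`,
#' `replicate`, `marine_count`, `freshwater_count`. One row per gene x tissue
#' x timepoint x replicate; the key must be unique. Timepoint is coded
#' 1 = early, 2 = late.
#'
#' @param path Path to the TSV file.
#' @return A data.frame (class `allelic_counts`).
#' @export
read_allelic_counts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(.count_cols, names(tab))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s",
                 path, paste(missing, collapse = ", ")))
  }
  tab <- tab[, .count_cols]
  for (col in c("timepoint", "replicate", "marine_count", "freshwater_count")) {
    vals <- suppressWarnings(as.numeric(tab[[col]]))
    .check_counts(vals, col, path)
    tab[[col]] <- as.integer(vals)
  }
  if (any(tab$replicate < 1L)) stop(path, ": replicate must be >= 1")
  key <- paste(tab$gene_id, tab$tissue, tab$timepoint, tab$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop(sprintf("%s: duplicated (gene, tissue, timepoint, replicate) key: %s",
                 path, gsub("\r", "/", dup)))
  }
  class(tab) <- c("allelic_counts", "data.frame")
  tab
}

#' Write a gene-level allelic count table
#' @param counts A data.frame with the allelic-count columns.
#' @param path Output path.
#' @export
write_allelic_counts <- function(counts, path) {
  write_results_tsv(counts[, .count_cols], path)
}

#' Read a site-level allelic count table
#'
#' Tab-separated with header columns `chrom`, `pos` (1-based), `gene_id`,
#' `marine_count`, `freshwater_count`; counts are pooled across libraries.
#'
#' @param path Path to the TSV file.
#' @return A data.frame (class `site_counts`).
#' @export
read_site_counts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(.site_cols, names(tab))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s",
                 path, paste(missing, collapse = ", ")))
  }
  tab <- tab[, .site_cols]
  for (col in c("pos", "marine_count", "freshwater_count")) {
    vals <- suppressWarnings(as.numeric(tab[[col]]))
    .check_counts(vals, col, path)
    tab[[col]] <- as.integer(vals)
  }
  if (any(tab$pos < 1L)) stop(path, ": pos must be >= 1 (1-based)")
  key <- paste(tab$chrom, tab$pos, sep = ":")
  if (anyDuplicated(key)) {
    stop(sprintf("%s: duplicated site: %s", path, key[duplicated(key)][1]))
  }
  class(tab) <- c("site_counts", "data.frame")
  tab
}

#' Write a site-level allelic count table
#' @param sites A data.frame with the site-count columns.
#' @param path Output path.
#' @export
write_site_counts <- function(sites, path) {
  write_results_tsv(sites[, .site_cols], path)
}

#' Read a BED interval file
#'
#' BED3+ with optional column 4 (name) and column 5 (score; the CSS Z-score
#' for `kind = "css_window"`). Coordinates are stored 0-based half-open,
#' exactly as in the file.
#'
#' @param path Path to the BED file.
#' @param kind One of `"gene"`, `"css_window"`, `"ecopeak"`, `"qtl"`.
#' @return A data.frame (class `interval_set`) with columns `chrom`, `start`,
#'   `end`, `name`, `score`, `kind`.
#' @export
read_bed <- function(path, kind = c("gene", "css_window", "ecopeak", "qtl")) {
  kind <- match.arg(kind)
  gr <- rtracklayer::import(path, format = "bed")
  n <- length(gr)
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # back to BED convention
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) as.character(gr$name) else sprintf("iv%06d", seq_len(n)),
    score = if (!is.null(gr$score)) as.numeric(gr$score) else rep(NA_real_, n),
    kind = rep(kind, n),
    stringsAsFactors = FALSE
  )
  if (any(out$start >= out$end)) {
    bad <- which(out$start >= out$end)[1]
    stop(sprintf("%s: empty or inverted interval at record %d (start >= end)",
                 path, bad))
  }
  if (kind == "css_window" && any(is.na(out$score))) {
    stop(path, ": css_window intervals require a numeric score (CSS Z)")
  }
  class(out) <- c("interval_set", "data.frame")
  out
}

#' Write an interval set as BED5
#' @param intervals An interval_set data.frame (0-based half-open).
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  score <- intervals$score
  score[is.na(score)] <- 0
  lines <- sprintf("%s\t%d\t%d\t%s\t%s",
                   intervals$chrom, intervals$start, intervals$end,
                   intervals$name, formatC(score, format = "g", digits = 10))
  writeLines(lines, path)
  invisible(path)
}

# interval_set (0-based half-open) -> GRanges (1-based closed)
intervals_to_granges <- function(intervals) {
  GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L, end = intervals$end),
    name = intervals$name, score = intervals$score
  )
}

#' Read gene sets with an ortholog map
#'
#' The set file has two columns (`set_id`, `source_gene`); the ortholog map
#' has two columns (`source_gene`, `target_gene`), one-to-many allowed. Each
#' set's members are the union of all target genes of its source members.
#' Source genes absent from the map are dropped with a warning.
#'
#' @param set_path Two-column TSV of set memberships (with header).
#' @param ortholog_path Optional two-column TSV mapping source to target gene
#'   IDs (with header). `NULL` means identity mapping.
#' @return A named list of character vectors (class `gene_sets`); names are
#'   set ids.
#' @export
read_gene_sets <- function(set_path, ortholog_path = NULL) {
  sets <- utils::read.delim(set_path, stringsAsFactors = FALSE)
  if (ncol(sets) < 2) stop(set_path, ": expected two columns (set_id, source_gene)")
  names(sets)[1:2] <- c("set_id", "source_gene")
  if (!is.null(ortholog_path)) {
    map <- utils::read.delim(ortholog_path, stringsAsFactors = FALSE)
    if (ncol(map) < 2) stop(ortholog_path, ": expected two columns (source_gene, target_gene)")
    names(map)[1:2] <- c("source_gene", "target_gene")
    unmapped <- setdiff(unique(sets$source_gene), unique(map$source_gene))
    if (length(unmapped)) {
      warning(sprintf("read_gene_sets: %d source gene(s) absent from ortholog map, dropped (e.g. %s)",
                      length(unmapped), unmapped[1]))
    }
    merged <- merge(sets, map, by = "source_gene")
    members <- split(merged$target_gene, merged$set_id)
  } else {
    members <- split(sets$source_gene, sets$set_id)
  }
  members <- lapply(members, function(g) sort(unique(g)))
  members <- members[vapply(members, length, 1L) > 0]
  if (length(members) == 0L) {
    stop("read_gene_sets: no gene set has any mapped member")
  }
  structure(members, class = "gene_sets")
}

#' Write gene sets as a two-column TSV
#' @param sets A named list of member vectors.
#' @param path Output path.
#' @export
write_gene_sets <- function(sets, path) {
  df <- data.frame(
    set_id = rep(names(sets), vapply(sets, length, 1L)),
    source_gene = unlist(sets, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  write_results_tsv(df, path)
}

#' Write a result table as TSV
#'
#' Deterministic output: fixed column order (as given), header always
#' present, floats rendered with 6 significant digits by default. Two writes
#' of the same table are byte-identical.
#'
#' @param table A data.frame.
#' @param path Output path.
#' @param digits Significant digits for numeric (non-integer) columns.
#' @export
write_results_tsv <- function(table, path, digits = 6) {
  tab <- as.data.frame(table)
  for (col in names(tab)) {
    if (is.double(tab[[col]])) {
      tab[[col]] <- formatC(tab[[col]], format = "g", digits = digits)
      tab[[col]][tab[[col]] %in% c("NA", " NA")] <- "NA"
    }
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}
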