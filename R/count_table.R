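#' Construct a validated taxon-by-sample count table
#'
#' The count table is the common currency of the package: an integer matrix of
#' sequencing read counts with taxa as rows and samples as columns. All
#' downstream stages (relative abundance, ICI, differential screens,
#' diversity) consume this structure.
#'
#' @param counts Numeric matrix of non-negative whole numbers, taxa in rows,
#'   samples in columns. Dimnames are used as identifiers unless overridden.
#' @param taxon_ids Optional character vector of row identifiers.
#' @param sample_ids Optional character vector of column identifiers.
#' @return An object of class `count_table`: an integer-valued matrix with
#'   unique row and column names.
#' @export
count_table <- function(counts, taxon_ids = rownames(counts),
                        sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(taxon_ids)) taxon_ids <- sprintf("T%d", seq_len(nrow(counts)))
  if (is.null(sample_ids)) sample_ids <- sprintf("S%d", seq_len(ncol(counts)))
  if (length(taxon_ids) != nrow(counts) || length(sample_ids) != ncol(counts))
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  storage.mode(counts) <- "double"
  bad <- which(!is.finite(counts) | counts < 0 | abs(counts - round(counts)) > 1e-8,
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "count table contains non-integer or negative cells, e.g. row '%s', column '%s'",
      taxon_ids[bad[1, 1]], sample_ids[bad[1, 2]]), call. = FALSE)
  }
  counts <- round(counts)
  if (anyDuplicated(taxon_ids))
    stop("duplicated taxon_ids: ", paste(unique(taxon_ids[duplicated(taxon_ids)]),
                                         collapse = ", "), call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicated sample_ids: ", paste(unique(sample_ids[duplicated(sample_ids)]),
                                          collapse = ", "), call. = FALSE)
  dimnames(counts) <- list(taxon_id = taxon_ids, sample_id = sample_ids)
  class(counts) <- c("count_table", "matrix", "array")
  counts
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d taxa x %d samples, %s total reads\n",
              nrow(x), ncol(x), format(sum(x), big.mark = ",")))
  invisible(x)
}

#' Validate a sample metadata table
#'
#' Metadata rows describe one sequenced sample each: which subject and age it
#' came from, the clinical group, and which sorted fraction it is. The IgA-seq
#' design requires a presort sample for every subject-age, and the sorted
#' fractions (`igapos`, `iganeg`) to occur as a pair or not at all.
#'
#' @param df Data frame with columns `sample_id`, `subject_id`, `group`
#'   (`control`/`celiac`), `age` (years), `fraction`
#'   (`presort`/`igapos`/`iganeg`).
#' @return The validated data frame with class `sample_metadata` prepended.
#' @export
sample_metadata <- function(df) {
  req <- c("sample_id", "subject_id", "group", "age", "fraction")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("metadata missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$sample_id <- as.character(df$sample_id)
  df$subject_id <- as.character(df$subject_id)
  df$group <- as.character(df$group)
  df$fraction <- as.character(df$fraction)
  df$age <- as.numeric(df$age)
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id in metadata", call. = FALSE)
  bad_grp <- setdiff(unique(df$group), c("control", "celiac"))
  if (length(bad_grp) > 0)
    stop("unknown group label(s): ", paste(bad_grp, collapse = ", "), call. = FALSE)
  bad_fr <- setdiff(unique(df$fraction), c("presort", "igapos", "iganeg"))
  if (length(bad_fr) > 0)
    stop("unknown fraction label(s): ", paste(bad_fr, collapse = ", "), call. = FALSE)
  key <- paste(df$subject_id, df$age, df$fraction)
  if (anyDuplicated(key))
    stop("(subject_id, age, fraction) not unique: ",
         key[anyDuplicated(key)], call. = FALSE)
  # presort present for each subject-age; sorted fractions come in pairs
  by_sub <- split(df$fraction, paste(df$subject_id, df$age))
  for (k in names(by_sub)) {
    fr <- by_sub[[k]]
    if (!"presort" %in% fr)
      stop("subject-age '", k, "' lacks a presort sample", call. = FALSE)
    if (xor("igapos" %in% fr, "iganeg" %in% fr))
      stop("subject-age '", k, "' has an unpaired sorted fraction", call. = FALSE)
  }
  if (!inherits(df, "sample_metadata")) class(df) <- c("sample_metadata", class(df))
  df
}

check_sample_join <- function(table_samples, meta_samples) {
  only_meta <- setdiff(meta_samples, table_samples)
  only_tab <- setdiff(table_samples, meta_samples)
  if (length(only_meta) > 0 || length(only_tab) > 0) {
    stop("sample mismatch between count table and metadata; ",
         if (length(only_meta) > 0)
           paste0("metadata-only: ", paste(only_meta, collapse = ", "), "; ") else "",
         if (length(only_tab) > 0)
           paste0("table-only: ", paste(only_tab, collapse = ", ")) else "",
         call. = FALSE)
  }
  invisible(TRUE)
}

# -- readers / writers ---------------------------------------------------

# File dialect: UTF-8 tab-separated, first header cell "taxon_id",
# '#'-prefixed lines ignored (used for provenance headers).

#' Read a taxon-by-sample count table (and optionally its metadata)
#'
#' @param path Path to a tab-separated matrix: header row of sample ids with
#'   leading cell `taxon_id`, one row per taxon. Lines starting with `#` are
#'   ignored. Alternatively a BIOM file when `format = "biom"` (requires the
#'   biomformat package; read-only).
#' @param metadata_path Optional path to a tab-separated metadata table with
#'   the [sample_metadata()] columns; when given, the sample sets must match
#'   exactly.
#' @param format `"tsv"` (canonical) or `"biom"`.
#' @return A `count_table`, or when `metadata_path` is given a list with
#'   elements `counts` and `metadata`.
#' @export
read_count_table <- function(path, metadata_path = NULL,
                             format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("BIOM input requires the 'biomformat' package", call. = FALSE)
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    tab <- count_table(m)
  } else {
    df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 1 || names(df)[1] != "taxon_id")
      stop("count table must have 'taxon_id' as its first column: ", path,
           call. = FALSE)
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (nrow(m) > 0 && !is.numeric(m)) {
      nonnum <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))) &
                        !is.na(m), arr.ind = TRUE)
      stop(sprintf("non-numeric cell at row '%s', column '%s'",
                   ids[nonnum[1, 1]], colnames(m)[nonnum[1, 2]]), call. = FALSE)
    }
    tab <- count_table(m, taxon_ids = ids, sample_ids = colnames(m))
  }
  if (is.null(metadata_path)) return(tab)
  meta <- read_sample_metadata(metadata_path)
  check_sample_join(colnames(tab), meta$sample_id)
  list(counts = tab, metadata = meta)
}

#' Write a count table as canonical TSV
#'
#' Round-trips exactly through [read_count_table()].
#'
#' @param table A `count_table`.
#' @param path Output path.
#' @param header Optional character vector of provenance lines, written as
#'   `#`-prefixed comments before the table.
#' @export
write_count_table <- function(table, path, header = NULL) {
  stopifnot(inherits(table, "count_table"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(c("taxon_id", colnames(table)), collapse = "\t"), con)
  if (nrow(table) > 0) {
    body <- apply(format(unclass(table), scientific = FALSE, trim = TRUE), 1,
                  paste, collapse = "\t")
    writeLines(paste(rownames(table), body, sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname read_count_table
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  sample_metadata(df)
}

#' @rdname write_count_table
#' @param metadata A `sample_metadata` data frame.
#' @export
write_sample_metadata <- function(metadata, path) {
  utils::write.table(as.data.frame(metadata), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Taxonomy table: ASV to rank-labelled lineage
#'
#' @param df Data frame with columns `taxon_id` and `lineage`
#'   (semicolon-delimited, kingdom to species; missing ranks may be empty).
#' @return Validated data frame of class `taxonomy_table`.
#' @export
taxonomy_table <- function(df) {
  if (!all(c("taxon_id", "lineage") %in% names(df)))
    stop("taxonomy requires columns taxon_id and lineage", call. = FALSE)
  df$taxon_id <- as.character(df$taxon_id)
  df$lineage <- as.character(df$lineage)
  if (anyDuplicated(df$taxon_id))
    stop("duplicated taxon_id in taxonomy", call. = FALSE)
  if (!inherits(df, "taxonomy_table")) class(df) <- c("taxonomy_table", class(df))
  df
}

#' @rdname taxonomy_table
#' @param path Path to a tab-separated taxonomy file.
#' @export
read_taxonomy <- function(path) {
  taxonomy_table(utils::read.delim(path, header = TRUE, sep = "\t",
                                   comment.char = "#", stringsAsFactors = FALSE))
}

#' @rdname taxonomy_table
#' @param taxonomy A `taxonomy_table`.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(as.data.frame(taxonomy), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Feature table of plasma analytes (metabolites or cytokines)
#'
#' Non-negative real matrix of normalized intensities, features in rows,
#' samples in columns; used by the volcano screen.
#'
#' @param values Non-negative numeric matrix.
#' @param feature_ids,sample_ids Optional identifiers (default: dimnames).
#' @return Matrix of class `feature_table`.
#' @export
feature_table <- function(values, feature_ids = rownames(values),
                          sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(feature_ids)) feature_ids <- sprintf("F%d", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- sprintf("S%d", seq_len(ncol(values)))
  if (any(!is.finite(values)) || any(values < 0))
    stop("feature table must be non-negative and finite", call. = FALSE)
  if (anyDuplicated(feature_ids)) stop("duplicated feature_ids", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("duplicated sample_ids", call. = FALSE)
  dimnames(values) <- list(feature_id = feature_ids, sample_id = sample_ids)
  class(values) <- c("feature_table", "matrix", "array")
  values
}

#' @rdname feature_table
#' @param path File path (tab-separated, first column `feature_id`).
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "feature_id")
    stop("feature table must have 'feature_id' as its first column", call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  feature_table(m, feature_ids = as.character(df[[1]]), sample_ids = colnames(m))
}

#' @rdname feature_table
#' @param features A `feature_table`.
#' @export
write_feature_table <- function(features, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("feature_id", colnames(features)), collapse = "\t"), con)
  if (nrow(features) > 0) {
    body <- apply(unclass(features), 1, function(r)
      paste(format(r, digits = 15, scientific = FALSE, trim = TRUE), collapse = "\t"))
    writeLines(paste(rownames(features), body, sep = "\t"), con)
  }
  invisible(path)
}

# -- agglomeration -------------------------------------------------------

TAXONOMIC_RANKS <- c("kingdom", "phylum", "class", "order", "family",
                     "genus", "species")

#' Agglomerate a count table at a taxonomic rank
#'
#' Counts of taxa sharing the same label at `rank` are summed. Taxa whose
#' lineage is empty at that rank are pooled into `"unclassified"` rather than
#' dropped, so per-sample read totals are conserved exactly (downstream
#' relative abundances depend on this).
#'
#' @param table A `count_table`.
#' @param taxonomy A `taxonomy_table` covering every taxon in `table`.
#' @param rank One of kingdom, phylum, class, order, family, genus, species.
#' @return A `count_table` with one row per rank label, rows ordered by first
#'   appearance in `table`.
#' @export
agglomerate <- function(table, taxonomy, rank) {
  stopifnot(inherits(table, "count_table"))
  taxonomy <- taxonomy_table(as.data.frame(taxonomy))
  if (!rank %in% TAXONOMIC_RANKS)
    stop("unknown rank '", rank, "'; expected one of: ",
         paste(TAXONOMIC_RANKS, collapse = ", "), call. = FALSE)
  missing_tax <- setdiff(rownames(table), taxonomy$taxon_id)
  if (length(missing_tax) > 0)
    stop("taxa missing from taxonomy: ",
         paste(utils::head(missing_tax, 5), collapse = ", "), call. = FALSE)
  idx <- match(rownames(table), taxonomy$taxon_id)
  parts <- strsplit(taxonomy$lineage[idx], ";", fixed = TRUE)
  k <- match(rank, TAXONOMIC_RANKS)
  label <- vapply(parts, function(p) {
    v <- if (length(p) >= k) trimws(p[k]) else ""
    if (is.na(v) || v == "") "unclassified" else v
  }, character(1))
  lv <- unique(label)
  agg <- rowsum(unclass(table), group = factor(label, levels = lv), reorder = FALSE)
  count_table(agg, taxon_ids = rownames(agg), sample_ids = colnames(table))
}
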