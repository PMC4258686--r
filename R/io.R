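#' Construct an abundance table
#'
#' The pipeline's central container: a samples x features matrix of
#' non-negative relative abundances with unique sample and feature labels and
#' a level tag saying whether features are genera or KEGG pathway/module ids.
#'
#' @param values numeric matrix, samples in rows, features in columns.
#' @param sample_ids,feature_ids optional label vectors; default to the
#'   matrix dimnames.
#' @param level one of `"genus"`, `"kegg_pathway"`, `"kegg_module"`.
#' @return an object of class `abundance_table` (a matrix with a `level`
#'   attribute).
#' @export
abundance_table <- function(values, sample_ids = rownames(values),
                            feature_ids = colnames(values),
                            level = c("genus", "kegg_pathway", "kegg_module")) {
  level <- match.arg(level)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(feature_ids)) feature_ids <- paste0("F", seq_len(ncol(values)))
  if (anyDuplicated(sample_ids))
    stop_validation("duplicate sample ids: %s",
                    paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(feature_ids))
    stop_validation("duplicate feature ids: %s",
                    paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  if (anyNA(values) || any(!is.finite(values)))
    stop_validation("abundance table contains missing or non-finite values")
  if (any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop_validation("negative abundance at sample '%s', feature '%s'",
                    sample_ids[idx[1L]], feature_ids[idx[2L]])
  }
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(values, level = level, class = c("abundance_table", "matrix", "array"))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d features (level: %s)\n",
              nrow(x), ncol(x), attr(x, "level")))
  invisible(x)
}

is_abundance_table <- function(x) inherits(x, "abundance_table")

#' Read an abundance table from TSV
#'
#' Accepts either a plain TSV (first column = row labels) or a
#' MetaPhlAn-style merged table (clade strings in the first column, samples
#' in the remaining columns).  For the MetaPhlAn dialect only genus-level
#' rows are kept: clade strings whose terminal rank is `g__` (higher ranks
#' and species/strain rows are dropped) and the label is stripped to the bare
#' genus name.  Lines starting with `#` are ignored, except a leading
#' `#SampleID` header line which is taken as the header.
#'
#' On-disk orientation is ambiguous for plain TSVs; by default it is guessed
#' (`#SampleID` header, or a first-column name containing "sample", means
#' samples-as-rows; otherwise features-as-rows is assumed, the MetaPhlAn
#' convention).  Set `orientation` explicitly to override.
#'
#' @param path file path.
#' @param dialect `"plain_tsv"` or `"metaphlan_merged"`.
#' @param orientation `"auto"`, `"samples_as_rows"` or `"features_as_rows"`.
#' @param level feature level tag, see [abundance_table()].
#' @return an [abundance_table()], always oriented samples x features.
#' @export
read_abundance_table <- function(path,
                                 dialect = c("plain_tsv", "metaphlan_merged"),
                                 orientation = c("auto", "samples_as_rows",
                                                 "features_as_rows"),
                                 level = c("genus", "kegg_pathway", "kegg_module")) {
  dialect <- match.arg(dialect)
  orientation <- match.arg(orientation)
  level <- match.arg(level)
  if (!file.exists(path)) stop_validation("file not found: %s", path)

  lines <- readLines(path, encoding = "UTF-8")
  header_is_hash <- length(lines) > 0L && grepl("^#SampleID\\b", lines[1L], ignore.case = TRUE)
  if (header_is_hash) lines[1L] <- sub("^#", "", lines[1L])
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) < 2L) stop_validation("no data rows in %s", path)
  df <- read.delim(text = paste(lines, collapse = "\n"), header = TRUE,
                   check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(df[[1L]])
  first_col <- names(df)[1L]
  body <- df[, -1L, drop = FALSE]
  if (!all(vapply(body, is.numeric, logical(1L))))
    stop_validation("non-numeric entries in the body of %s", path)
  m <- as.matrix(body)
  rownames(m) <- labels

  if (dialect == "metaphlan_merged") {
    # keep clades whose last rank is genus: "...|g__Name" with nothing below
    keep <- grepl("\\|g__[^|]+$", labels) | grepl("^g__[^|]+$", labels)
    if (!any(keep)) stop_validation("no genus-level (g__) rows found in %s", path)
    m <- m[keep, , drop = FALSE]
    rownames(m) <- sub("^.*g__", "", rownames(m))
    m <- t(m)  # metaphlan merged tables are features x samples
  } else {
    samples_as_rows <- switch(orientation,
      samples_as_rows = TRUE,
      features_as_rows = FALSE,
      auto = header_is_hash || grepl("sample", first_col, ignore.case = TRUE))
    if (!samples_as_rows) m <- t(m)
  }
  abundance_table(m, level = level)
}

#' Write an abundance table to TSV (samples as rows)
#'
#' @param x an [abundance_table()].
#' @param path output file path.
#' @export
write_abundance_table <- function(x, path) {
  stopifnot(is_abundance_table(x))
  df <- data.frame(sample_id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a twin design table
#'
#' The design maps every sample to its subject, monozygotic twin pair and
#' time point.  Validation enforces: each (subject, time point) sampled at
#' most once; every pair has exactly two subjects; time points in \{1, 2\}.
#'
#' @param path TSV with columns `sample_id`, `subject_id`, `pair_id`,
#'   `time_point` (extra columns are kept).
#' @return a `twin_design` data.frame; attributes `n_pairs` and
#'   `n_longitudinal` hold the pair count and the number of subjects sampled
#'   at both time points.
#' @export
read_twin_design <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   comment.char = "#")
  twin_design(df)
}

#' Validate a twin design data.frame
#'
#' @param df data.frame with columns `sample_id`, `subject_id`, `pair_id`,
#'   `time_point`.
#' @return the validated `twin_design`.
#' @export
twin_design <- function(df) {
  needed <- c("sample_id", "subject_id", "pair_id", "time_point")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop_validation("design is missing column(s): %s", paste(missing_cols, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$subject_id <- as.character(df$subject_id)
  df$pair_id <- as.character(df$pair_id)
  df$time_point <- as.integer(df$time_point)
  if (anyDuplicated(df$sample_id))
    stop_validation("duplicate sample_id in design")
  if (!all(df$time_point %in% c(1L, 2L)))
    stop_validation("time_point must be 1 or 2")
  st <- paste(df$subject_id, df$time_point)
  if (anyDuplicated(st))
    stop_validation("subject sampled more than once at the same time point: %s",
                    st[duplicated(st)][1L])
  subj_per_pair <- tapply(df$subject_id, df$pair_id,
                          function(s) length(unique(s)))
  bad <- names(subj_per_pair)[subj_per_pair != 2L]
  if (length(bad))
    stop_validation("pair(s) without exactly two subjects: %s",
                    paste(bad, collapse = ", "))
  n_times <- tapply(df$time_point, df$subject_id, function(t) length(unique(t)))
  structure(df, class = c("twin_design", "data.frame"),
            n_pairs = length(subj_per_pair),
            n_longitudinal = sum(n_times == 2L))
}

#' @export
print.twin_design <- function(x, ...) {
  cat(sprintf("twin_design: %d samples, %d MZ pairs, %d subjects sampled at both time points\n",
              nrow(x), attr(x, "n_pairs"), attr(x, "n_longitudinal")))
  invisible(x)
}

#' Read a host metadata table
#'
#' Holds anthropometric/biochemical traits in clinical units, food-group
#' intakes (g/day) and daily energy + nutrient intakes for each sample.
#' Column families are recognized by prefix: `food_` for food groups,
#' `nutr_` for nutrients, plus an `energy` column; every other non-id
#' numeric column is a trait.  Missing values stay missing (`NA`) and are
#' never imputed; diet analyses use complete cases.
#'
#' @param path TSV with a `sample_id` column.
#' @param food_prefix,nutrient_prefix,energy_col family column conventions.
#' @return a `metadata_table` data.frame with attributes `trait_cols`,
#'   `food_cols`, `nutrient_cols`, `energy_col`.
#' @export
read_metadata_table <- function(path, food_prefix = "food_",
                                nutrient_prefix = "nutr_",
                                energy_col = "energy") {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   comment.char = "#")
  metadata_table(df, food_prefix = food_prefix,
                 nutrient_prefix = nutrient_prefix, energy_col = energy_col)
}

#' Validate a metadata data.frame
#'
#' @inheritParams read_metadata_table
#' @param df data.frame with a `sample_id` column.
#' @return the validated `metadata_table`.
#' @export
metadata_table <- function(df, food_prefix = "food_",
                           nutrient_prefix = "nutr_", energy_col = "energy") {
  if (!"sample_id" %in% names(df))
    stop_validation("metadata is missing the sample_id column")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop_validation("duplicate sample_id in metadata")
  num <- names(df)[vapply(df, is.numeric, logical(1L))]
  food_cols <- grep(paste0("^", food_prefix), num, value = TRUE)
  nutrient_cols <- grep(paste0("^", nutrient_prefix), num, value = TRUE)
  trait_cols <- setdiff(num, c(food_cols, nutrient_cols, energy_col))
  for (cl in c(food_cols, nutrient_cols, intersect(energy_col, num))) {
    v <- df[[cl]]
    if (any(v < 0, na.rm = TRUE))
      stop_validation("negative intake in column %s", cl)
  }
  structure(df, class = c("metadata_table", "data.frame"),
            trait_cols = trait_cols, food_cols = food_cols,
            nutrient_cols = nutrient_cols,
            energy_col = if (energy_col %in% names(df)) energy_col else NULL)
}

#' @export
print.metadata_table <- function(x, ...) {
  cat(sprintf("metadata_table: %d samples; %d traits, %d food groups, %d nutrients%s\n",
              nrow(x), length(attr(x, "trait_cols")), length(attr(x, "food_cols")),
              length(attr(x, "nutrient_cols")),
              if (is.null(attr(x, "energy_col"))) "" else " + energy"))
  invisible(x)
}

#' Write a metadata table to TSV
#' @param x a `metadata_table`.
#' @param path output file path.
#' @export
write_metadata_table <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a twin design table to TSV
#' @param x a `twin_design`.
#' @param path output file path.
#' @export
write_twin_design <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write clustering assignments to TSV
#'
#' One row per sample: enterotype label, the raw cluster under each scanned
#' metric (if several results are given) and the per-sample silhouette width
#' of the primary result.  Reading the file back with
#' [read_assignments()] reproduces the assignments losslessly.
#'
#' @param result a `clustering_result` (see [select_k()]), or a named list
#'   of them keyed by metric.
#' @param path output file path.
#' @export
write_assignments <- function(result, path) {
  results <- if (inherits(result, "clustering_result")) {
    setNames(list(result), result$metric)
  } else result
  primary <- results[[1L]]
  df <- data.frame(sample_id = primary$sample_ids,
                   enterotype = primary$assignments,
                   stringsAsFactors = FALSE)
  for (nm in names(results))
    df[[paste0("cluster_", nm)]] <- results[[nm]]$assignments
  df$silhouette_width <- primary$silhouette_widths
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a TSV written by [write_assignments()]
#' @param path file path.
#' @return a data.frame with at least `sample_id` and `enterotype`.
#' @export
read_assignments <- function(path) {
  read.delim(path, header = TRUE, stringsAsFactors = FALSE)
}

#' Join abundance, design and metadata on shared samples
#'
#' Restricts all three tables to the intersection of their sample ids (the
#' metadata may be `NULL`), preserving the abundance table's order, and
#' reports how many ids each table dropped.
#'
#' @param abundance an [abundance_table()].
#' @param design a `twin_design`.
#' @param metadata optional `metadata_table`.
#' @return list with elements `abundance`, `design`, `metadata`, `dropped`
#'   (named counts of ids missing from the intersection).
#' @export
join_cohort <- function(abundance, design, metadata = NULL) {
  ids <- intersect(rownames(abundance), design$sample_id)
  if (!is.null(metadata)) ids <- intersect(ids, metadata$sample_id)
  ids <- rownames(abundance)[rownames(abundance) %in% ids]
  if (length(ids) == 0L) stop_validation("no samples shared across tables")
  dropped <- c(abundance = nrow(abundance) - length(ids),
               design = nrow(design) - length(ids),
               metadata = if (is.null(metadata)) 0L else nrow(metadata) - length(ids))
  if (any(dropped > 0L))
    message(sprintf("join_cohort: dropped ids not shared by all tables (%s)",
                    paste(names(dropped), dropped, sep = "=", collapse = ", ")))
  ab <- abundance_table(unclass(abundance)[ids, , drop = FALSE],
                        level = attr(abundance, "level"))
  de_df <- as.data.frame(design)[match(ids, design$sample_id), , drop = FALSE]
  rownames(de_df) <- NULL
  # a join may leave a pair with one subject; recompute counts without
  # re-imposing the two-subjects-per-pair input invariant
  n_times <- tapply(de_df$time_point, de_df$subject_id,
                    function(t) length(unique(t)))
  de <- structure(de_df, class = c("twin_design", "data.frame"),
                  n_pairs = length(unique(de_df$pair_id)),
                  n_longitudinal = sum(n_times == 2L))
  md <- if (is.null(metadata)) NULL else {
    metadata_table(as.data.frame(metadata)[match(ids, metadata$sample_id), , drop = FALSE])
  }
  list(abundance = ab, design = de, metadata = md, dropped = dropped)
}
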