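#' Construct and validate a replicate-level OTU count table
#'
#' @param sample_id Sample identifier.
#' @param counts Integer matrix, rows = OTUs (rownames set, one row being
#'   the calibrator), columns = replicates.
#' @param ic_otu_id Row name of the internal calibrator.
#' @param sample_type `"sample"` or `"NEC"`.
#' @param location,month Optional metadata carried with the table.
#' @return An `otu_count_table`.
#' @export
otu_count_table <- function(sample_id, counts, ic_otu_id = "IC",
                            sample_type = c("sample", "NEC"),
                            location = NA_character_, month = NA_integer_) {
  sample_type <- match.arg(sample_type)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("`counts` must have OTU row names")
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate OTU ids in count table")
  }
  if (!ic_otu_id %in% rownames(counts)) {
    stop("calibrator row '", ic_otu_id, "' missing from count table")
  }
  if (ncol(counts) < 1L) stop("need at least 1 replicate column")
  if (!is.numeric(counts) || anyNA(counts)) {
    stop("read counts must be numeric and complete")
  }
  if (any(counts < 0)) stop("read counts must be >= 0")
  if (any(counts != round(counts))) stop("read counts must be integers")
  storage.mode(counts) <- "integer"
  structure(
    list(sample_id = sample_id, counts = counts, ic_otu_id = ic_otu_id,
         sample_type = sample_type, location = location,
         month = as.integer(month)),
    class = "otu_count_table"
  )
}

# header lines stamped on every table the package writes
header_lines <- function(config = NULL) {
  h <- if (is.null(config)) "none" else {
    fnv1a(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA))
  }
  c(paste0("# micmon ", tool_version()), paste0("# config_hash: ", h))
}

#' Write a data frame as TSV with a version/config-hash header
#'
#' @param df Data frame.
#' @param path Output path.
#' @param config Optional configuration object hashed into the header.
#' @export
write_table_tsv <- function(df, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines(config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_table_tsv()] (comment lines skipped)
#' @param path Input path.
#' @return data.frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write one sample's count table (otu_id, replicate_1..k)
#' @param table An `otu_count_table`.
#' @param path Output path.
#' @param config Optional config for the header hash.
#' @export
write_count_table <- function(table, path, config = NULL) {
  stopifnot(inherits(table, "otu_count_table"))
  df <- data.frame(otu_id = rownames(table$counts), table$counts,
                   check.names = FALSE)
  write_table_tsv(df, path, config)
}

#' Read a replicate-level count table from TSV
#'
#' Expects a column `otu_id` plus one integer column per replicate; the
#' calibrator row must be present. Duplicate OTU ids, missing calibrator,
#' and negative or non-integer counts each raise a distinct error.
#'
#' @param path TSV path.
#' @param sample_id Defaults to the file name without extension.
#' @param sample_type `"sample"` or `"NEC"`.
#' @param ic_otu_id Calibrator row id (default `"IC"`).
#' @param location,month Optional metadata.
#' @return An `otu_count_table`.
#' @export
read_count_table <- function(path, sample_id = NULL,
                             sample_type = c("sample", "NEC"),
                             ic_otu_id = "IC",
                             location = NA_character_, month = NA_integer_) {
  sample_type <- match.arg(sample_type)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  df <- read_table_tsv(path)
  if (!"otu_id" %in% names(df)) stop("count table must have an `otu_id` column")
  counts <- as.matrix(df[, setdiff(names(df), "otu_id"), drop = FALSE])
  rownames(counts) <- df$otu_id
  otu_count_table(sample_id = sample_id, counts = counts,
                  ic_otu_id = ic_otu_id, sample_type = sample_type,
                  location = location, month = month)
}

#' Write a simulated dataset to a directory
#'
#' One count TSV per sample and NEC, a `metadata.tsv`, the ground-truth
#' copies as `truth.tsv` (long format), the contamination profile, and the
#' configuration as JSON.
#'
#' @param dataset A [simulate_dataset()] bundle (or a `sim_reads` plus
#'   optional `truth`).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  reads <- if (inherits(dataset, "sim_reads")) dataset else dataset$reads
  truth <- if (inherits(dataset, "sim_reads")) NULL else dataset$truth
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- reads$config
  for (tbl in c(reads$samples, unname(reads$necs))) {
    write_count_table(tbl, file.path(dir, paste0(tbl$sample_id, ".tsv")), cfg)
  }
  write_table_tsv(reads$metadata, file.path(dir, "metadata.tsv"), cfg)
  if (!is.null(truth)) {
    tr <- as.data.frame.table(truth$copies, responseName = "true_copies")
    names(tr) <- c("otu_id", "location", "month", "true_copies")
    write_table_tsv(tr, file.path(dir, "truth.tsv"), cfg)
    write_table_tsv(
      data.frame(otu_id = names(truth$contamination),
                 contamination_copies = unname(truth$contamination)),
      file.path(dir, "contamination.tsv"), cfg
    )
  }
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write an absolute profile as TSV plus a JSON sidecar
#'
#' The TSV holds `otu_id`, `copies_per_100ul`, `n_replicates_detected`; the
#' sidecar records the limit of detection and replicate validity flags.
#'
#' @param profile An `absolute_profile`.
#' @param path TSV path; the sidecar is written next to it as `.json`.
#' @param config Optional config for the header hash.
#' @export
write_profile <- function(profile, path, config = NULL) {
  stopifnot(inherits(profile, "absolute_profile"))
  df <- data.frame(
    otu_id = names(profile$copies),
    copies_per_100ul = unname(profile$copies),
    n_replicates_detected = unname(profile$n_replicates_detected)
  )
  write_table_tsv(df, path, config)
  sidecar <- sub("\\.[^.]*$", ".json", path)
  jsonlite::write_json(
    list(sample_id = profile$sample_id, lod = profile$lod,
         n_valid_replicates = profile$n_valid_replicates),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
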