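#' Read a probe-annotated count dataset
#'
#' Reads the three tab-delimited tables that describe one run — counts
#' (probes x lanes), probe annotation, and lane metadata — cross-validates
#' them, and assembles a dataset ready for [run_normalization()]. All files
#' are UTF-8 TSV with `.` decimal separators and a header row.
#'
#' * `counts.tsv`: first column `probe_id`, one further column per lane.
#' * `probes.tsv`: columns `probe_id`, `target`, `probe_class`
#'   (endogenous/positive/negative/igg/housekeeping), `is_phospho`
#'   (true/false, empty for non-endogenous probes).
#' * `samples.tsv`: columns `lane_id`, `patient_id`, `specimen`
#'   (core/excision), `surgery` (lumpectomy/mastectomy/unknown),
#'   `tumour_size_mm`, `dilution_tag` (the last three may be empty).
#'
#' Rows may appear in any order; the dataset is canonically ordered by
#' probe_id (annotation order) and lane_id (metadata order).
#'
#' @param counts_path,probes_path,samples_path paths to the three tables.
#' @return a list of class `"npx_dataset"` with elements `counts` (an
#'   [count_matrix()] at stage `"raw"`), `probes` and `samples` (tibbles).
#' @export
read_dataset <- function(counts_path, probes_path, samples_path) {
  for (p in c(counts_path, probes_path, samples_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  counts_df <- readr::read_tsv(counts_path, show_col_types = FALSE,
                               progress = FALSE, comment = "#")
  probes <- readr::read_tsv(probes_path, show_col_types = FALSE,
                            progress = FALSE,
                            col_types = readr::cols(.default = "c"))
  samples <- readr::read_tsv(samples_path, show_col_types = FALSE,
                             progress = FALSE,
                             col_types = readr::cols(.default = "c"))
  npx_dataset(counts_df, probes, samples)
}

#' Assemble and validate a dataset from in-memory tables
#'
#' Same validation as [read_dataset()] but starting from data frames (or a
#' counts matrix), so simulated cohorts can enter the pipeline without a
#' round-trip through disk.
#'
#' @param counts data frame whose first column is `probe_id`, or a numeric
#'   matrix with probe rownames and lane colnames.
#' @param probes probe annotation data frame (see [read_dataset()]).
#' @param samples lane metadata data frame (see [read_dataset()]).
#' @return a validated `"npx_dataset"` list.
#' @export
npx_dataset <- function(counts, probes, samples) {
  probes <- validate_probes(probes)
  samples <- validate_samples(samples)
  if (is.matrix(counts)) {
    values <- counts
  } else {
    counts <- as_tibble(counts)
    if (names(counts)[1] != "probe_id") {
      stop("first counts column must be 'probe_id'", call. = FALSE)
    }
    values <- as.matrix(counts[-1])
    rownames(values) <- as.character(counts$probe_id)
  }
  if (!is.numeric(values)) {
    bad <- which(!vapply(as.data.frame(values), is.numeric, logical(1)))
    stop("non-numeric count column(s): ",
         paste(colnames(values)[bad], collapse = ", "), call. = FALSE)
  }
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop(sprintf("negative count at probe '%s', lane '%s' (value %g)",
                 rownames(values)[neg[1, 1]], colnames(values)[neg[1, 2]],
                 values[neg[1, , drop = FALSE]]), call. = FALSE)
  }
  only_counts <- setdiff(rownames(values), probes$probe_id)
  only_annot <- setdiff(probes$probe_id, rownames(values))
  if (length(only_counts) || length(only_annot)) {
    stop("probe cross-reference failure; in counts only: [",
         paste(only_counts, collapse = ", "), "]; in annotation only: [",
         paste(only_annot, collapse = ", "), "]", call. = FALSE)
  }
  only_lanes <- setdiff(colnames(values), samples$lane_id)
  only_meta <- setdiff(samples$lane_id, colnames(values))
  if (length(only_lanes) || length(only_meta)) {
    stop("lane cross-reference failure; in counts only: [",
         paste(only_lanes, collapse = ", "), "]; in metadata only: [",
         paste(only_meta, collapse = ", "), "]", call. = FALSE)
  }
  # canonical order: annotation / metadata row order
  values <- values[probes$probe_id, samples$lane_id, drop = FALSE]
  structure(
    list(counts = count_matrix(values, "raw"), probes = probes,
         samples = samples),
    class = "npx_dataset"
  )
}

validate_probes <- function(probes) {
  probes <- as_tibble(probes)
  need <- c("probe_id", "target", "probe_class", "is_phospho")
  if (!all(need %in% names(probes))) {
    stop("probe table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  classes <- c("endogenous", "positive", "negative", "igg", "housekeeping")
  bad <- setdiff(unique(probes$probe_class), classes)
  if (length(bad)) {
    stop("unknown probe_class: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(probes$probe_id)) {
    stop("duplicated probe_id in annotation: ",
         paste(unique(probes$probe_id[duplicated(probes$probe_id)]),
               collapse = ", "), call. = FALSE)
  }
  for (cls in c("positive", "negative", "housekeeping")) {
    if (!any(probes$probe_class == cls)) {
      stop("annotation needs at least one probe of class '", cls, "'",
           call. = FALSE)
    }
  }
  probes$is_phospho <- parse_logical_col(probes$is_phospho)
  probes$is_phospho[probes$probe_class != "endogenous"] <- NA
  probes
}

parse_logical_col <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  out
}

validate_samples <- function(samples) {
  samples <- as_tibble(samples)
  need <- c("lane_id", "patient_id", "specimen", "surgery",
            "tumour_size_mm", "dilution_tag")
  if (!all(need %in% names(samples))) {
    stop("sample table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(samples$lane_id)) {
    stop("duplicated lane_id in metadata", call. = FALSE)
  }
  bad <- setdiff(unique(samples$specimen), c("core", "excision"))
  if (length(bad)) stop("unknown specimen: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  samples$surgery <- ifelse(is.na(samples$surgery) | samples$surgery == "",
                            "unknown", samples$surgery)
  bad <- setdiff(unique(samples$surgery),
                 c("lumpectomy", "mastectomy", "unknown"))
  if (length(bad)) stop("unknown surgery: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  samples$tumour_size_mm <- suppressWarnings(as.numeric(samples$tumour_size_mm))
  if (any(!is.na(samples$tumour_size_mm) & samples$tumour_size_mm <= 0)) {
    stop("tumour_size_mm must be positive where present", call. = FALSE)
  }
  samples$dilution_tag <- as.character(samples$dilution_tag)
  samples$dilution_tag[samples$dilution_tag %in% ""] <- NA_character_
  key <- paste(samples$patient_id, samples$specimen, samples$dilution_tag,
               sep = "\r")
  if (anyDuplicated(key)) {
    dup <- samples[duplicated(key) | duplicated(key, fromLast = TRUE), ]
    stop("multiple lanes for the same (patient, specimen, dilution_tag): ",
         paste(unique(paste0(dup$patient_id, "/", dup$specimen)),
               collapse = ", "), call. = FALSE)
  }
  samples
}

#' Read an IHC score table
#'
#' Tab-delimited with columns `patient_id`, `specimen`, `protein`, `scale`
#' (`h_score` 0-300, `percent_positive` 0-100, or `ordinal_0_to_3`), and
#' `value`. Values are checked against their declared scale bounds.
#'
#' @param path path to `ihc.tsv`.
#' @return tibble of IHC records (possibly zero rows).
#' @export
read_ihc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ihc <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(value = "d", .default = "c"))
  validate_ihc(ihc)
}

validate_ihc <- function(ihc) {
  ihc <- as_tibble(ihc)
  need <- c("patient_id", "specimen", "protein", "scale", "value")
  if (!all(need %in% names(ihc))) {
    stop("IHC table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(ihc) == 0) return(ihc)
  bounds <- list(h_score = c(0, 300), percent_positive = c(0, 100),
                 ordinal_0_to_3 = c(0, 3))
  bad_scale <- setdiff(unique(ihc$scale), names(bounds))
  if (length(bad_scale)) {
    stop("unknown IHC scale token: ", paste(bad_scale, collapse = ", "),
         call. = FALSE)
  }
  ihc$value <- as.numeric(ihc$value)
  for (i in seq_len(nrow(ihc))) {
    b <- bounds[[ihc$scale[i]]]
    if (is.na(ihc$value[i]) || ihc$value[i] < b[1] || ihc$value[i] > b[2]) {
      stop(sprintf(
        "IHC value %s out of bounds [%g, %g] for scale '%s' (row %d, %s/%s)",
        format(ihc$value[i]), b[1], b[2], ihc$scale[i], i,
        ihc$patient_id[i], ihc$protein[i]), call. = FALSE)
    }
  }
  ihc
}

#' Write or read a staged matrix as TSV
#'
#' The matrix is written as tab-delimited text with the probe ids in the
#' first column and the processing stage recorded on a leading comment line
#' (`# stage: ...`). `read_matrix()` restores ids, values and stage; the
#' round-trip is exact to readr's shortest-round-trip double formatting.
#'
#' @param m matrix from [count_matrix()].
#' @param path output path.
#' @return `write_matrix()` returns `path` invisibly; `read_matrix()` returns
#'   an `npx_matrix`.
#' @export
write_matrix <- function(m, path) {
  stopifnot(inherits(m, "npx_matrix"))
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open for writing: ", path, " (", conditionMessage(e), ")",
         call. = FALSE)
  })
  close(con)
  readr::write_lines(paste0("# stage: ", matrix_stage(m)), path)
  df <- tibble::as_tibble(as.data.frame(unclass(m)), rownames = "probe_id")
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readr::read_lines(path, n_max = 1)
  stage <- sub("^# stage: *", "", first)
  if (identical(stage, first)) {
    stop("missing '# stage:' header line in ", path, call. = FALSE)
  }
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  values <- as.matrix(df[-1])
  rownames(values) <- df$probe_id
  count_matrix(values, stage = stage)
}

#' Write the per-lane metadata / probe annotation / IHC tables
#'
#' Thin wrappers around `readr::write_tsv()` using the package's fixed
#' dialect, provided so simulated cohorts can be exported in the same form
#' [read_dataset()] expects.
#'
#' @param x a tibble (probes, samples, or IHC records).
#' @param path output path.
#' @export
write_table <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}
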