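#' Count and expression matrices with stage provenance
#'
#' Count matrices are ordinary numeric matrices (probes in rows, lanes in
#' columns, both dimnames set) carrying a `stage` attribute that records how
#' far along the normalization chain the values are. Stages advance strictly
#' in the order `raw` -> `positive_normalized` -> `background_corrected` ->
#' `housekeeping_normalized` -> `log2`; each normalization step checks the
#' incoming stage so matrices cannot silently skip a step. Values must be
#' non-negative at every stage except `log2`.
#'
#' @param values numeric matrix, probes x lanes, with rownames (probe ids)
#'   and colnames (lane ids).
#' @param stage one of `"raw"`, `"positive_normalized"`,
#'   `"background_corrected"`, `"housekeeping_normalized"`, `"log2"`.
#' @return `count_matrix()` returns the matrix with class `"npx_matrix"` and
#'   the stage attribute set; `matrix_stage()` returns the stage string.
#' @examples
#' m <- count_matrix(matrix(1:4, 2, dimnames = list(c("a", "b"), c("l1", "l2"))))
#' matrix_stage(m)
#' @export
count_matrix <- function(values, stage = "raw") {
  stage <- match.arg(stage, npx_stages())
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("count matrix needs probe rownames and lane colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicated probe_id in matrix rows", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicated lane_id in matrix columns", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("count matrix contains non-finite values", call. = FALSE)
  }
  if (stage != "log2" && any(values < 0)) {
    stop("negative values are not allowed at stage '", stage, "'", call. = FALSE)
  }
  structure(values, stage = stage, class = c("npx_matrix", class(values)))
}

npx_stages <- function() {
  c("raw", "positive_normalized", "background_corrected",
    "housekeeping_normalized", "log2")
}

#' @rdname count_matrix
#' @param m a matrix created by [count_matrix()].
#' @export
matrix_stage <- function(m) {
  st <- attr(m, "stage")
  if (is.null(st)) stop("matrix has no stage attribute", call. = FALSE)
  st
}

# internal: require a stage, with the calling operation named in the error
check_stage <- function(m, expected, op) {
  st <- matrix_stage(m)
  if (!st %in% expected) {
    stop(sprintf("%s expects stage %s, got '%s' (stages advance in order: %s)",
                 op, paste(sQuote(expected), collapse = " or "), st,
                 paste(npx_stages(), collapse = " -> ")), call. = FALSE)
  }
  invisible(m)
}

# internal: rebuild with a new stage, preserving dimnames
restage <- function(values, template, stage) {
  dimnames(values) <- dimnames(template)
  count_matrix(values, stage = stage)
}

#' Tidy an expression or count matrix into long format
#'
#' @param x matrix from [count_matrix()].
#' @param ... unused.
#' @return a tibble with columns `probe_id`, `lane_id`, `value` and `stage`.
#' @export
tidy.npx_matrix <- function(x, ...) {
  tibble(
    probe_id = rep(rownames(x), times = ncol(x)),
    lane_id = rep(colnames(x), each = nrow(x)),
    value = as.vector(unclass(x)[, , drop = FALSE]),
    stage = matrix_stage(x)
  )
}
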