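# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

fail <- function(...) stop(..., call. = FALSE)

#' Derive a reproducible substream seed
#'
#' Maps a master seed and a stream label to a 32-bit seed, so that named
#' stages (simulation blocks, resampling, ordination, ...) draw from
#' independent, individually re-runnable streams.
#'
#' @param seed Integer master seed.
#' @param name Character stream label.
#' @return A single integer in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.character(name), length(name) == 1L)
  m <- 2147483647
  h <- 17
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% m
  as.integer((h * 48271 + (abs(as.double(seed)) %% m) * 69621) %% m)
}

# Run `code` under the substream seed, then restore the caller's RNG state.
with_substream <- function(seed, name, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(derive_seed(seed, name))
  }
  force(code)
}

#' Transform log of an expression matrix
#'
#' Each preprocessing step appends a tag describing itself, so the
#' provenance of a matrix is auditable downstream.
#'
#' @param x A matrix produced by the preprocessing functions.
#' @return Character vector of applied steps (empty if none recorded).
#' @export
transform_log <- function(x) attr(x, "transform_log") %||% character()

add_transform <- function(x, step) {
  attr(x, "transform_log") <- c(transform_log(x), step)
  x
}

# preserves transform_log (and other attrs worth keeping) across subsetting
keep_log <- function(new, old) {
  attr(new, "transform_log") <- transform_log(old)
  new
}

row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(NA_real_, nrow(x)))
  rowSums((x - rowMeans(x))^2) / (n - 1)
}

row_sds <- function(x) sqrt(row_vars(x))

# validated gene x sample count matrix
as_count_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) fail("counts must be numeric")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    fail("counts must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts))) fail("duplicated gene ids in counts")
  if (anyDuplicated(colnames(counts))) fail("duplicated sample ids in counts")
  if (ncol(counts) < 2L) fail("need at least 2 samples")
  if (any(counts < 0)) fail("counts must be non-negative")
  counts
}

check_metadata <- function(meta, counts = NULL) {
  if (!is.data.frame(meta)) fail("metadata must be a data.frame")
  need <- c("sample_id", "population", "temperature", "replicate")
  miss <- setdiff(need, names(meta))
  if (length(miss)) fail("metadata lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) fail("duplicated sample_id in metadata")
  if (!is.null(counts)) {
    if (!setequal(colnames(counts), meta$sample_id))
      fail("sample ids of counts and metadata disagree")
    meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  }
  meta$population <- factor(meta$population,
                            levels = unique(as.character(meta$population)))
  meta$temperature <- factor(meta$temperature)
  meta
}
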