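# Internal helpers shared across modules.

# Wide expression tibble (transcript_id + one numeric column per sample)
# -> numeric matrix with transcript rownames.
expr_matrix <- function(x) {
  stopifnot(is.data.frame(x), ncol(x) >= 2)
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(x[[1]])
  m
}

# Inverse of expr_matrix().
expr_tibble <- function(m, id = "transcript_id") {
  out <- as_tibble(as.data.frame(m, check.names = FALSE))
  out <- dplyr::bind_cols(tibble(!!id := rownames(m)), out)
  out
}

sample_ids <- function(x) colnames(x)[-1]

# Row variances without matrixStats; ok for the matrix sizes used here.
row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

assert_expr_tbl <- function(x, arg = deparse(substitute(x))) {
  if (!is.data.frame(x) || ncol(x) < 2) {
    abort(sprintf("`%s` must be a wide expression tibble (id column + samples).", arg))
  }
  ids <- as.character(x[[1]])
  if (anyDuplicated(ids)) {
    abort(sprintf(
      "`%s` has duplicated transcript ids: %s", arg,
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  if (anyDuplicated(sample_ids(x))) {
    abort(sprintf("`%s` has duplicated sample ids.", arg))
  }
  vals <- as.matrix(x[, -1, drop = FALSE])
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    abort(sprintf("`%s` must contain only finite numeric values.", arg))
  }
  invisible(x)
}

# Accept a per-sample index as tibble(sample_id, index) or a named vector.
index_vector <- function(index, samples) {
  if (is.data.frame(index)) {
    if (!all(c("sample_id", "index") %in% names(index))) {
      abort("`index` data frame needs columns sample_id and index.")
    }
    v <- setNames(index$index, index$sample_id)
  } else if (is.numeric(index) && !is.null(names(index))) {
    v <- index
  } else {
    abort("`index` must be a tibble(sample_id, index) or a named numeric vector.")
  }
  missing <- setdiff(samples, names(v))
  if (length(missing) > 0) {
    abort(paste0("`index` is missing samples: ", paste(missing, collapse = ", ")))
  }
  v <- v[samples]
  if (any(!is.finite(v)) || any(v <= 0)) {
    abort("leukocyte index values must be finite and positive.")
  }
  v
}

`%||%` <- rlang::`%||%`
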