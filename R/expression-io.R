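#' Read a log2 expression matrix from TSV
#'
#' Expects a tab-separated file whose header row carries sample identifiers,
#' whose first column carries transcript identifiers, and whose body is
#' numeric log2 abundance.  The file is validated strictly: duplicate
#' transcript or sample identifiers, ragged rows and non-numeric body cells
#' are errors (naming the offending transcript/sample where possible).
#'
#' @param path Path to the TSV file.
#' @param platform Either `"mrna"` or `"mirna"`; stored as the
#'   `"platform"` attribute of the result.
#' @return A tibble with a `transcript_id` column followed by one numeric
#'   column per sample, in file order.
#' @seealso [write_expression_matrix()] for the inverse operation.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("transcript_id\ts1\ts2", "g1\t1.5\t2", "g2\t0\t-1"), tf)
#' read_expression_matrix(tf)
read_expression_matrix <- function(path, platform = c("mrna", "mirna")) {
  platform <- match.arg(platform)
  raw <- suppressWarnings(readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, na = character()
  ))  # parsing problems are re-raised as errors below
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(sprintf(
      "malformed TSV `%s`: %d parsing problem(s), first at row %d (%s).",
      path, nrow(probs), probs$row[1], probs$expected[1]
    ))
  }
  if (ncol(raw) < 2) abort(sprintf("`%s` needs an id column plus >=1 sample.", path))
  ids <- raw[[1]]
  if (anyDuplicated(ids)) {
    abort(sprintf(
      "duplicated transcript id(s) in `%s`: %s", path,
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  if (anyDuplicated(names(raw)[-1])) {
    abort(sprintf("duplicated sample id(s) in `%s` header.", path))
  }
  body <- purrr::imap(raw[-1], function(col, nm) {
    x <- suppressWarnings(as.numeric(col))
    bad <- which(!is.finite(x))
    if (length(bad) > 0) {
      abort(sprintf(
        "non-numeric cell in `%s`: transcript `%s`, sample `%s` (value \"%s\").",
        path, ids[bad[1]], nm, col[bad[1]]
      ))
    }
    x
  })
  out <- dplyr::bind_cols(tibble(transcript_id = ids), as_tibble(body))
  attr(out, "platform") <- platform
  out
}

#' Write an expression matrix as TSV
#'
#' @param x Wide expression tibble (`transcript_id` + sample columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  assert_expr_tbl(x)
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read a cohort annotation table
#'
#' The annotation TSV has one row per sample with columns `sample_id`,
#' `group` (one of normal/nm/dm/pm/ibm), and optional `he_grade` (ordinal
#' 0-4 inflammation grade from H&E histology), `pfa` (perifascicular
#' atrophy flag) and `muscle_site`.
#'
#' @param path Path to the TSV file.
#' @return A tibble, one row per sample.
#' @export
read_annotation <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_annotation(ann)
}

#' @rdname read_annotation
#' @param ann Annotation data frame to validate.
#' @export
validate_annotation <- function(ann) {
  if (!all(c("sample_id", "group") %in% names(ann))) {
    abort("annotation needs columns `sample_id` and `group`.")
  }
  ann$group <- tolower(as.character(ann$group))
  bad <- setdiff(unique(ann$group), c("normal", "nm", "dm", "pm", "ibm"))
  if (length(bad) > 0) {
    abort(paste0("unknown group label(s): ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(ann$sample_id)) abort("duplicated sample_id in annotation.")
  if ("he_grade" %in% names(ann)) {
    g <- ann$he_grade[!is.na(ann$he_grade)]
    if (length(g) > 0 && (!all(g == round(g)) || any(g < 0 | g > 4))) {
      abort("he_grade must be an integer in 0..4 when present.")
    }
  }
  as_tibble(ann)
}

#' Log2 fold change against the normal-control reference
#'
#' The reference for each transcript is the arithmetic mean of its log2
#' values over the normal-control samples (a geometric mean on the linear
#' scale).  Every sample, including the normal controls themselves, is
#' expressed as its deviation from that pooled reference, so normal-sample
#' columns average to zero per transcript.
#'
#' @param expr Wide expression tibble.
#' @param annotation Cohort annotation with at least two `group == "normal"`
#'   samples present in `expr`.
#' @return A tibble of the same shape holding log2 fold changes; the
#'   per-transcript normal-mean reference is attached as attribute
#'   `"normal_mean"` (named numeric), and the normal sample ids as
#'   `"normal_samples"`.
#' @export
log2_fold_change_vs_normal <- function(expr, annotation) {
  assert_expr_tbl(expr)
  annotation <- validate_annotation(annotation)
  normals <- intersect(
    annotation$sample_id[annotation$group == "normal"],
    sample_ids(expr)
  )
  if (length(normals) < 2) {
    abort("need >=2 normal-control samples in `expr` to form the reference.")
  }
  m <- expr_matrix(expr)
  ref <- rowMeans(m[, normals, drop = FALSE])
  fc <- expr_tibble(m - ref)
  attr(fc, "normal_mean") <- ref
  attr(fc, "normal_samples") <- normals
  attr(fc, "platform") <- attr(expr, "platform")
  fc
}

#' Normalize a TLDA-style miRNA Ct table to relative log2 abundance
#'
#' Implements endogenous-control delta-Ct normalization: per sample,
#' `dCt_g = Ct_g - mean(Ct over control transcripts)`, reported on the
#' log2 abundance scale as `-dCt` (so a target 3 cycles below the control
#' mean maps to +3, i.e. an 8-fold relative level).  Undetected wells
#' (`NA` Ct) are imputed to `undetected_ceiling` before normalization.
#'
#' @param ct Wide tibble of Ct values (`transcript_id` + sample columns);
#'   `NA` marks undetected wells.
#' @param control_ids Transcript ids of the endogenous-control rows (e.g.
#'   a small nucleolar RNA such as RNU48); all must be present.
#' @param undetected_ceiling Ct value imputed for undetected wells
#'   (default 40 cycles).
#' @return A wide expression tibble of relative log2 abundance with
#'   platform attribute `"mirna"`.
#' @export
normalize_tlda_ct <- function(ct, control_ids, undetected_ceiling = 40) {
  if (!is.data.frame(ct) || ncol(ct) < 2) abort("`ct` must be a wide Ct tibble.")
  ids <- as.character(ct[[1]])
  missing <- setdiff(control_ids, ids)
  if (length(missing) > 0) {
    abort(paste0("control transcript(s) missing from Ct table: ",
                 paste(missing, collapse = ", ")))
  }
  m <- as.matrix(ct[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m[is.na(m)] <- undetected_ceiling
  if (any(!is.finite(m))) abort("Ct values must be finite or NA (undetected).")
  ctrl_mean <- colMeans(m[control_ids, , drop = FALSE])
  out <- expr_tibble(-sweep(m, 2, ctrl_mean))
  attr(out, "platform") <- "mirna"
  out
}

#' Read or write gene sets in GMT format
#'
#' One set per line: name, description, then member identifiers, all
#' tab-separated.  Members are de-duplicated within a set.
#'
#' @param path GMT file path.
#' @return `read_gmt()`: a named list of character vectors with the set
#'   descriptions attached as attribute `"descriptions"`.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 3
  if (any(short)) abort("each GMT line needs name, description and >=1 member.")
  sets <- purrr::map(fields, ~ unique(.x[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(names(sets))) abort("duplicated gene-set names in GMT.")
  attr(sets, "descriptions") <-
    setNames(vapply(fields, `[[`, character(1), 2), names(sets))
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param descriptions Optional named character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% attr(sets, "descriptions") %||%
    setNames(rep("", length(sets)), names(sets))
  lines <- purrr::imap_chr(sets, function(members, nm) {
    paste(c(nm, descriptions[[nm]] %||% "", unique(members)), collapse = "\t")
  })
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write a list of result tables to a directory
#'
#' Data frames are written as TSV named `<name>.tsv`; bare lists as JSON
#' named `<name>.json`.  Serialization is deterministic so a read-write
#' round trip is the identity on formatted values.
#'
#' @param objects Named list of tibbles and/or lists.
#' @param out_dir Output directory (created if absent).
#' @return Named character vector of file paths, invisibly.
#' @export
write_tables <- function(objects, out_dir) {
  stopifnot(is.list(objects), !is.null(names(objects)), all(nzchar(names(objects))))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create output directory `%s`.", out_dir))
  }
  paths <- purrr::imap_chr(objects, function(obj, nm) {
    if (is.data.frame(obj)) {
      p <- file.path(out_dir, paste0(nm, ".tsv"))
      readr::write_tsv(obj, p, progress = FALSE)
    } else {
      p <- file.path(out_dir, paste0(nm, ".json"))
      jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA, null = "null")
    }
    p
  })
  invisible(paths)
}
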