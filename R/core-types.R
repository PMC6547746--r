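DISEASE_LEVELS <- c("affected", "unaffected", "asymptomatic_carrier", "control")
SEX_LEVELS <- c("F", "M")
COHORT_LEVELS <- c("twin", "case_control")
HIL_LEVELS <- c("HC", "IC", "ICshore", "LC")

SHEET_COLUMNS <- c(
  "sample_id", "individual_id", "twin_set_id", "disease_status", "sex",
  "age_at_collection", "collection_index", "replicate_group", "cohort"
)

#' Construct and validate a sample sheet
#'
#' A sample sheet holds one row per assayed sample and encodes the twin,
#' longitudinal and technical-replicate structure of a cohort: which
#' individual and twin set a sample belongs to, the disease status of the
#' individual, sex, age at blood collection, the ordinal collection index
#' (longitudinal time point) and a replicate group shared by technical
#' replicates of the same collection.
#'
#' @param df data.frame with columns `sample_id`, `individual_id`,
#'   `twin_set_id`, `disease_status`, `sex`, `age_at_collection`,
#'   `collection_index`, `replicate_group`, `cohort`.
#' @return A validated data.frame of class `twin_sample_sheet`.
#' @export
sample_sheet <- function(df) {
  missing_cols <- setdiff(SHEET_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("sample sheet is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[, SHEET_COLUMNS]
  for (col in c("sample_id", "individual_id", "twin_set_id",
                "replicate_group")) {
    df[[col]] <- as.character(df[[col]])
  }
  df$disease_status <- as.character(df$disease_status)
  df$sex <- as.character(df$sex)
  df$cohort <- as.character(df$cohort)
  df$age_at_collection <- as.numeric(df$age_at_collection)
  df$collection_index <- as.integer(df$collection_index)

  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in sheet: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]),
               collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(df$disease_status), DISEASE_LEVELS)
  if (length(bad)) stop("unknown disease_status: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  bad <- setdiff(unique(df$sex), SEX_LEVELS)
  if (length(bad)) stop("unknown sex: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  bad <- setdiff(unique(df$cohort), COHORT_LEVELS)
  if (length(bad)) stop("unknown cohort: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (any(df$collection_index < 1L, na.rm = TRUE)) {
    stop("collection_index must be >= 1", call. = FALSE)
  }
  # twin sets need at least two individuals
  twin <- df[df$cohort == "twin", , drop = FALSE]
  if (nrow(twin)) {
    n_ind <- tapply(twin$individual_id, twin$twin_set_id,
                    function(x) length(unique(x)))
    if (any(n_ind < 2)) {
      stop("twin set(s) with fewer than two individuals: ",
           paste(names(n_ind)[n_ind < 2], collapse = ", "), call. = FALSE)
    }
  }
  # replicate groups must not span individuals or collections
  grp <- split(df[, c("individual_id", "collection_index")], df$replicate_group)
  for (g in names(grp)) {
    if (length(unique(grp[[g]]$individual_id)) > 1 ||
        length(unique(grp[[g]]$collection_index)) > 1) {
      stop("replicate_group '", g,
           "' spans multiple individuals or collections", call. = FALSE)
    }
  }
  rownames(df) <- NULL
  class(df) <- c("twin_sample_sheet", "data.frame")
  df
}

#' Read a sample sheet from CSV/TSV
#'
#' @param path file path; delimiter inferred from extension (`.tsv` uses tab,
#'   everything else comma).
#' @return validated `twin_sample_sheet`.
#' @export
read_sample_sheet <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  # read everything as character ("F" for female must not become FALSE);
  # sample_sheet() coerces the numeric columns
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  sample_sheet(df)
}

#' Write a sample sheet to CSV
#'
#' @param sheet a `twin_sample_sheet`.
#' @param path output path.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(as.data.frame(sheet)[, SHEET_COLUMNS], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

check_matrix_kind <- function(mat, kind) {
  switch(kind,
    beta = {
      rng <- range(mat, na.rm = TRUE)
      if (rng[1] < 0 || rng[2] > 1) {
        stop("beta values outside [0,1]: range ",
             paste(signif(rng, 4), collapse = " .. "), call. = FALSE)
      }
    },
    detection_p = {
      rng <- range(mat, na.rm = TRUE)
      if (rng[1] < 0 || rng[2] > 1) {
        stop("detection p-values outside [0,1]", call. = FALSE)
      }
    },
    counts = {
      if (anyNA(mat)) stop("count matrix may not contain missing values",
                           call. = FALSE)
      if (any(mat < 0)) stop("negative counts", call. = FALSE)
      if (any(mat != round(mat))) {
        stop("non-integer counts found", call. = FALSE)
      }
    },
    stop("unknown matrix kind: ", kind, call. = FALSE)
  )
  invisible(TRUE)
}

#' Read a probes/genes-by-samples matrix
#'
#' Reads a dense TSV/CSV matrix whose first column (`id`) holds the row
#' identifiers (probes or genes) and whose remaining columns are samples.
#' Empty cells and the token `NA` are stored as missing (disallowed for
#' counts).
#'
#' @param path file path; delimiter inferred from extension.
#' @param kind one of `"beta"` (methylation fractions in \[0,1\]),
#'   `"detection_p"` (detection p-values in \[0,1\]) or `"counts"`
#'   (nonnegative integers).
#' @return numeric matrix with row and column names; attribute `kind` records
#'   the matrix type.
#' @export
read_matrix <- function(path, kind = c("beta", "detection_p", "counts")) {
  kind <- match.arg(kind)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate row identifiers", call. = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    stop("matrix contains non-numeric cells", call. = FALSE)
  }
  rownames(mat) <- ids
  check_matrix_kind(mat, kind)
  attr(mat, "kind") <- kind
  mat
}

#' Write a matrix in the package's dense TSV layout
#'
#' @param mat numeric matrix with row and column names.
#' @param path output path (tab-separated, row id column named `id`).
#' @export
write_matrix <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' Convert beta values to M-values
#'
#' M-values are the logit2 of methylation fractions,
#' \eqn{M = \log_2(\beta / (1 - \beta))}. Fractions are clipped into
#' \eqn{[\epsilon, 1 - \epsilon]} first so boundary values map to finite
#' M-values; missing cells propagate.
#'
#' @param beta numeric matrix (or vector) of methylation fractions in \[0,1\].
#' @param epsilon clipping bound in (0, 0.5); default `1e-6`.
#' @return matrix (or vector) of M-values, same shape and dimnames.
#' @export
beta_to_m <- function(beta, epsilon = 1e-6) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 ||
      epsilon <= 0 || epsilon >= 0.5) {
    stop("epsilon must be a single value in (0, 0.5)", call. = FALSE)
  }
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  m <- log2(b / (1 - b))
  if (is.matrix(beta)) dimnames(m) <- dimnames(beta)
  m
}

#' Reorder matrix columns to sample-sheet order
#'
#' Columns are reordered to follow the sheet; matrix columns absent from the
#' sheet are dropped with a warning, and a sheet sample absent from the
#' matrix is an error.
#'
#' @param mat matrix with sample columns.
#' @param sheet a `twin_sample_sheet`.
#' @return matrix with columns in sheet order.
#' @export
align_matrix_to_sheet <- function(mat, sheet) {
  want <- sheet$sample_id
  absent <- setdiff(want, colnames(mat))
  if (length(absent)) {
    stop("sheet sample(s) absent from matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(colnames(mat), want)
  if (length(extra)) {
    warning("dropping matrix column(s) not in sheet: ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  out <- mat[, want, drop = FALSE]
  attr(out, "kind") <- attr(mat, "kind")
  out
}

#' Construct and validate a probe annotation table
#'
#' @param df data.frame with columns `probe_id`, `chromosome`, `position`,
#'   `genes` (semicolon-separated symbols, may be empty), `distance_to_tss`,
#'   `hil_category` (one of HC, IC, ICshore, LC — the CpG-density classes),
#'   and logical flags `cross_hybridising`, `sex_chromosome`, `snp_overlap`.
#' @return validated data.frame of class `probe_annotation`.
#' @export
probe_annotation <- function(df) {
  need <- c("probe_id", "chromosome", "position", "genes", "distance_to_tss",
            "hil_category", "cross_hybridising", "sex_chromosome",
            "snp_overlap")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("annotation missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[, need]
  df$probe_id <- as.character(df$probe_id)
  if (anyDuplicated(df$probe_id)) stop("duplicate probe_id in annotation",
                                       call. = FALSE)
  df$genes <- as.character(df$genes)
  df$genes[is.na(df$genes)] <- ""
  bad <- setdiff(unique(df$hil_category), HIL_LEVELS)
  if (length(bad)) stop("unknown hil_category: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  for (fl in c("cross_hybridising", "sex_chromosome", "snp_overlap")) {
    df[[fl]] <- as.logical(df[[fl]])
  }
  class(df) <- c("probe_annotation", "data.frame")
  df
}

#' Read a probe annotation TSV
#' @param path file path (tab-separated with the annotation columns).
#' @return validated `probe_annotation`.
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""), quote = "")
  probe_annotation(df)
}

#' Write a probe annotation TSV
#' @param annot a `probe_annotation`.
#' @param path output path.
#' @export
write_probe_annotation <- function(annot, path) {
  utils::write.table(as.data.frame(annot), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

# split a semicolon-separated gene field into symbols (may be empty)
split_genes <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(g) g[nzchar(g)])
}
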