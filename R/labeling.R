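#' Read a phenotype table
#'
#' CSV with header `sample,suvr,tracer,diagnosis,case_control,visit` (columns
#' beyond `sample` optional). When a sample has several rows, the row with the
#' largest `visit` value is kept (last-visit selection).
#'
#' @param path CSV file path.
#' @return A data.frame of class `phenotype_table`, one row per sample.
#' @export
read_phenotype_table <- function(path) {
  if (!file.exists(path)) stop("phenotype table not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  phenotype_table(df)
}

#' @param df data.frame with at least a `sample` column.
#' @rdname read_phenotype_table
#' @export
phenotype_table <- function(df) {
  if (!"sample" %in% names(df)) stop("phenotype table needs a 'sample' column", call. = FALSE)
  df$sample <- as.character(df$sample)
  if (any(is.na(df$sample) | !nzchar(df$sample))) {
    stop("every phenotype row needs a sample id", call. = FALSE)
  }
  if ("visit" %in% names(df) && anyDuplicated(df$sample)) {
    df <- df[order(df$sample, df$visit), , drop = FALSE]
    df <- df[!duplicated(df$sample, fromLast = TRUE), , drop = FALSE]
  }
  if (anyDuplicated(df$sample)) {
    stop("duplicate sample ids in phenotype table (and no 'visit' column to disambiguate)",
         call. = FALSE)
  }
  if ("suvr" %in% names(df)) {
    has_suvr <- !is.na(df$suvr)
    if (!"tracer" %in% names(df) && any(has_suvr)) {
      stop("rows with SUVR values need a 'tracer' column", call. = FALSE)
    }
    if ("tracer" %in% names(df) && any(has_suvr & (is.na(df$tracer) | !nzchar(df$tracer)))) {
      stop("rows with SUVR values must have a tracer", call. = FALSE)
    }
  }
  rownames(df) <- NULL
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Amyloid-PET positivity labels from SUVR
#'
#' Labels a subject amyloid-positive (1) when the SUVR of its tracer reaches
#' the tracer-specific threshold: 1.11 for florbetapir, 1.27 for PiB. The
#' comparison is inclusive (`>=`) by default; rows without a SUVR value are
#' excluded.
#'
#' @param pheno a [phenotype_table()].
#' @param thresholds named numeric vector of per-tracer cutoffs.
#' @param inclusive use `>=` (default) rather than `>` at the boundary.
#' @return Named integer vector (sample id -> 0/1), class `label_vector`.
#' @export
label_pet <- function(pheno,
                      thresholds = c(florbetapir = 1.11, pib = 1.27),
                      inclusive = TRUE) {
  stopifnot(all(c("suvr", "tracer") %in% names(pheno)))
  keep <- !is.na(pheno$suvr)
  p <- pheno[keep, , drop = FALSE]
  tr <- tolower(trimws(p$tracer))
  unknown <- setdiff(unique(tr), names(thresholds))
  if (length(unknown)) {
    stop("unknown tracer value(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cut <- thresholds[tr]
  lab <- if (inclusive) as.integer(p$suvr >= cut) else as.integer(p$suvr > cut)
  label_vector(stats::setNames(lab, p$sample))
}

#' Combined PET-and-diagnosis labels
#'
#' Restricts PET labels to the concordant subset: amyloid-positive subjects
#' with a Dementia diagnosis keep label 1; amyloid-negative cognitively
#' normal (CN) subjects keep label 0; everyone else is dropped. Labels are
#' never flipped.
#'
#' @param pet a `label_vector` from [label_pet()].
#' @param pheno a [phenotype_table()] with a `diagnosis` column
#'   (`CN` / `MCI` / `Dementia`).
#' @return A `label_vector` over the retained subset.
#' @export
label_pet_dx <- function(pet, pheno) {
  stopifnot("diagnosis" %in% names(pheno))
  dx <- stats::setNames(pheno$diagnosis, pheno$sample)[names(pet)]
  keep <- (pet == 1L & !is.na(dx) & dx == "Dementia") |
          (pet == 0L & !is.na(dx) & dx == "CN")
  label_vector(pet[keep])
}

#' Case/control labels
#'
#' @param pheno a [phenotype_table()] with a `case_control` column
#'   (`case` / `control`).
#' @return A `label_vector`; rows with missing values are dropped with a
#'   warning.
#' @export
label_case_control <- function(pheno) {
  stopifnot("case_control" %in% names(pheno))
  cc <- tolower(trimws(as.character(pheno$case_control)))
  cc[cc %in% c("", "na")] <- NA
  bad <- setdiff(stats::na.omit(unique(cc)), c("case", "control"))
  if (length(bad)) stop("unknown case_control value(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (anyNA(cc)) {
    warning(sprintf("dropping %d sample(s) with missing case_control", sum(is.na(cc))))
  }
  keep <- !is.na(cc)
  label_vector(stats::setNames(as.integer(cc[keep] == "case"), pheno$sample[keep]))
}

#' Label vector constructor
#'
#' @param x named integer vector with values in \{0, 1\}; names are sample ids
#'   (1 = positive class).
#' @return `x` with class `label_vector`.
#' @export
label_vector <- function(x) {
  if (is.null(names(x)) && length(x) > 0L) stop("labels must be named by sample id", call. = FALSE)
  if (anyDuplicated(names(x))) stop("duplicate sample ids in labels", call. = FALSE)
  if (length(x) && !all(x %in% c(0L, 1L))) stop("labels must be 0 or 1", call. = FALSE)
  structure(stats::setNames(as.integer(x), names(x)), class = "label_vector")
}
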