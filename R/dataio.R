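## Reading abundance/metadata tables, quality filters, age/BMI
## categorisation, and stratified fold construction.

KP_AGE_LEVELS <- c("infant", "children_adolescents", "young_adult",
                   "middle_aged", "senior", "elderly")
KP_BMI_LEVELS <- c("underweight", "healthy_weight", "overweight", "obesity")
KP_GENDER_LEVELS <- c("female", "male")

#' Read a sample-by-species relative-abundance table
#'
#' Expects a delimited file with samples in rows: a header row of species ids,
#' a first column of sample ids, and a numeric body on the percent scale
#' (each row sums to ~100 before quality filtering).
#'
#' @param path Path to a TSV or CSV file (delimiter sniffed from the first
#'   line).
#' @return A numeric matrix (samples x species) with sample ids as rownames
#'   and species ids as colnames.
#' @export
read_abundance <- function(path) {
  delim <- sniff_delim(path)
  df <- utils::read.delim(path, sep = delim, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("abundance table needs a sample-id column plus at least one species column")
  ids <- as.character(df[[1L]])
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & nzchar(v))
      if (length(bad) > 0L)
        stop(sprintf("non-numeric abundance value '%s' at sample '%s', species '%s'",
                     v[bad[1L]], ids[bad[1L]], colnames(body)[j]), call. = FALSE)
      body[[j]] <- num
    }
  }
  mat <- as.matrix(body)
  if (anyNA(mat)) {
    idx <- which(is.na(mat), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing abundance value at sample '%s', species '%s'",
                 ids[idx[1L]], colnames(mat)[idx[2L]]), call. = FALSE)
  }
  if (any(mat < 0)) {
    idx <- which(mat < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative abundance at sample '%s', species '%s'",
                 ids[idx[1L]], colnames(mat)[idx[2L]]), call. = FALSE)
  }
  rownames(mat) <- ids
  mat
}

#' Write an abundance matrix as TSV
#'
#' Inverse of [read_abundance()] (round-trip identity up to numeric
#' formatting).
#' @param mat Numeric matrix, samples x species.
#' @param path Output path.
#' @export
write_abundance <- function(mat, path) {
  df <- data.frame(sample_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop samples with low total relative abundance
#'
#' Removes rows whose abundance sum (percent scale) is strictly below the
#' threshold; samples exactly at the threshold are kept.
#'
#' @param mat Abundance matrix from [read_abundance()].
#' @param threshold Minimum row sum to keep, in percent (default 90).
#' @return The filtered matrix.
#' @export
filter_samples <- function(mat, threshold = 90) {
  keep <- rowSums(mat) >= threshold
  if (!any(keep)) warning("all samples fall below the abundance-sum threshold")
  mat[keep, , drop = FALSE]
}

#' Drop samples whose phenotype has too few samples
#'
#' Removes every sample whose phenotype label occurs strictly fewer than
#' `min_samples` times.  The rule is applied uniformly to all labels
#' (including healthy controls, which in practice always clear the bar).
#'
#' @param meta Metadata data frame with a `phenotype` column.
#' @param min_samples Minimum per-phenotype sample count (default 50).
#' @return The filtered data frame with unused phenotype levels dropped.
#' @export
filter_rare_phenotypes <- function(meta, min_samples = 50) {
  counts <- table(meta$phenotype)
  keep_levels <- names(counts)[counts >= min_samples]
  out <- meta[meta$phenotype %in% keep_levels, , drop = FALSE]
  out$phenotype <- droplevels(factor(out$phenotype))
  out
}

#' Categorise age in years into the six age classes
#'
#' Bins: infant (age <= 3), children_adolescents (3 < age <= 18),
#' young_adult (18 < age <= 35), middle_aged (35 < age <= 50),
#' senior (50 < age <= 65), elderly (age > 65).
#'
#' @param age Numeric vector of ages in years (>= 0; `NA` passes through).
#' @return A factor with the six age-class levels.
#' @export
categorize_age <- function(age) {
  if (any(age < 0, na.rm = TRUE)) stop("age must be non-negative")
  cls <- cut(age, breaks = c(-Inf, 3, 18, 35, 50, 65, Inf),
             labels = KP_AGE_LEVELS, right = TRUE)
  factor(as.character(cls), levels = KP_AGE_LEVELS)
}

#' Categorise BMI into the four standard classes
#'
#' Bins: underweight (BMI < 18.5), healthy_weight (18.5 <= BMI < 25),
#' overweight (25 <= BMI < 30), obesity (BMI >= 30).
#'
#' @param bmi Numeric vector of BMI values in kg/m^2 (> 0; `NA` passes
#'   through).
#' @return A factor with the four BMI-class levels.
#' @export
categorize_bmi <- function(bmi) {
  if (any(bmi <= 0, na.rm = TRUE)) stop("BMI must be positive")
  cls <- cut(bmi, breaks = c(-Inf, 18.5, 25, 30, Inf),
             labels = KP_BMI_LEVELS, right = FALSE)
  factor(as.character(cls), levels = KP_BMI_LEVELS)
}

kp_to_level <- function(x, levels, what) {
  x <- trimws(as.character(x))
  x[x %in% c("", "NA", "na", "NaN")] <- NA
  bad <- !is.na(x) & !x %in% levels
  if (any(bad))
    stop(sprintf("unknown %s value(s): %s", what,
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  factor(x, levels = levels)
}

#' Read a per-sample metadata table
#'
#' Expects a delimited file with columns `sample_id`, `age`, `gender`, `bmi`,
#' `body_site`, `phenotype`, `project_id`.  `age` and `bmi` may be raw
#' numeric values (categorised on load via [categorize_age()] /
#' [categorize_bmi()]) or pre-categorised class strings.  Missing metadata
#' are encoded as empty cells or the literal `NA`; the phenotype must be
#' present for every sample.
#'
#' @param path Path to a TSV/CSV file.
#' @return A data frame with columns `sample_id`, `age_class`, `gender`,
#'   `bmi_class`, `body_site`, `phenotype`, `project_id`; metadata columns
#'   are factors with `NA` for missing values.
#' @export
read_metadata <- function(path) {
  delim <- sniff_delim(path)
  df <- utils::read.delim(path, sep = delim, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  required <- c("sample_id", "age", "gender", "bmi", "body_site",
                "phenotype", "project_id")
  missing_cols <- setdiff(required, colnames(df))
  if (length(missing_cols) > 0L)
    stop("metadata table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  ## cell-wise: numeric entries are categorised, strings must be class labels
  to_class <- function(x, categorize, levels, what) {
    x_chr <- trimws(as.character(x))
    x_chr[x_chr %in% c("", "NA", "na", "NaN")] <- NA
    suppressWarnings(num <- as.numeric(x_chr))
    out <- rep(NA_character_, length(x_chr))
    if (any(!is.na(num)))
      out[!is.na(num)] <- as.character(categorize(num[!is.na(num)]))
    rest <- which(is.na(num) & !is.na(x_chr))
    if (length(rest) > 0L) {
      bad <- !x_chr[rest] %in% levels
      if (any(bad))
        stop(sprintf("unknown %s value(s): %s", what,
                     paste(unique(x_chr[rest][bad]), collapse = ", ")),
             call. = FALSE)
      out[rest] <- x_chr[rest]
    }
    factor(out, levels = levels)
  }
  out <- data.frame(
    sample_id = as.character(df$sample_id),
    age_class = to_class(df$age, categorize_age, KP_AGE_LEVELS, "age class"),
    gender = kp_to_level(df$gender, KP_GENDER_LEVELS, "gender"),
    bmi_class = to_class(df$bmi, categorize_bmi, KP_BMI_LEVELS, "BMI class"),
    body_site = factor(as.character(df$body_site)),
    phenotype = factor(as.character(df$phenotype)),
    project_id = factor(as.character(df$project_id)),
    stringsAsFactors = FALSE)
  if (anyNA(out$phenotype))
    stop("phenotype must be present for every sample")
  out
}

#' Assemble an aligned microbiome dataset
#'
#' Pairs an abundance matrix with its metadata table, aligning rows by sample
#' id.  Abundances are stored on the percent scale used by the quality
#' filters; when `renormalize = TRUE` (default) each row is rescaled to sum
#' to 1 immediately before entering the model.
#'
#' @param abundance Numeric matrix from [read_abundance()].
#' @param meta Data frame from [read_metadata()].
#' @param renormalize Renormalise rows to sum to 1 at model input.
#' @return An object of class `kp_dataset`.
#' @export
microbiome_dataset <- function(abundance, meta, renormalize = TRUE) {
  idx <- match(rownames(abundance), meta$sample_id)
  if (anyNA(idx))
    stop("samples missing from metadata: ",
         paste(utils::head(rownames(abundance)[is.na(idx)], 5), collapse = ", "))
  meta <- meta[idx, , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(abundance = abundance, meta = meta,
                 species = colnames(abundance),
                 renormalize = isTRUE(renormalize)),
            class = "kp_dataset")
}

#' @export
print.kp_dataset <- function(x, ...) {
  cat(sprintf("kp_dataset: %d samples x %d species, %d phenotype classes\n",
              nrow(x$abundance), ncol(x$abundance),
              nlevels(x$meta$phenotype)))
  obs <- vapply(c("age_class", "gender", "bmi_class", "body_site"),
                function(col) mean(!is.na(x$meta[[col]])), numeric(1))
  cat("metadata observed fraction: ",
      paste(sprintf("%s=%.2f", sub("_class", "", names(obs)), obs),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

## Model-input matrix: percent-scale abundances optionally renormalised to
## per-sample proportions.
model_matrix <- function(dataset) {
  x <- dataset$abundance
  if (isTRUE(dataset$renormalize)) {
    s <- rowSums(x)
    s[s == 0] <- 1
    x <- x / s
  }
  x
}

subset_dataset <- function(dataset, idx) {
  structure(list(abundance = dataset$abundance[idx, , drop = FALSE],
                 meta = dataset$meta[idx, , drop = FALSE],
                 species = dataset$species,
                 renormalize = dataset$renormalize),
            class = "kp_dataset")
}

#' Stratified cross-validation folds
#'
#' Assigns samples to `k` folds so that each phenotype's counts differ by at
#' most one across folds (each class is shuffled and dealt round-robin from a
#' random starting fold).
#'
#' @param phenotypes Factor or character vector of phenotype labels.
#' @param k Number of folds (default 5).
#' @param seed Optional integer seed making the assignment deterministic.
#' @return An integer vector of fold indices in `1..k`, one per sample.
#' @export
stratified_folds <- function(phenotypes, k = 5, seed = NULL) {
  if (k < 2) stop("k must be at least 2")
  phenotypes <- as.factor(phenotypes)
  counts <- table(phenotypes)
  if (min(counts) < k)
    warning(sprintf("smallest class has %d samples, fewer than k = %d folds",
                    min(counts), k))
  with_seed(seed, {
    folds <- integer(length(phenotypes))
    for (cl in levels(phenotypes)) {
      idx <- which(phenotypes == cl)
      idx <- idx[sample.int(length(idx))]
      start <- sample.int(k, 1L)
      folds[idx] <- ((start - 1L + seq_along(idx) - 1L) %% k) + 1L
    }
    folds
  })
}

#' Split a dataset by project membership
#'
#' Partitions samples into train/test datasets by their `project_id`, for
#' project-held-out evaluation (testing on studies entirely absent from
#' training).
#'
#' @param dataset A `kp_dataset`.
#' @param train_projects,test_projects Disjoint character vectors of project
#'   ids.
#' @return A list with elements `train` and `test` (both `kp_dataset`).
#' @export
split_by_project <- function(dataset, train_projects, test_projects) {
  overlap <- intersect(train_projects, test_projects)
  if (length(overlap) > 0L)
    stop("train and test project sets overlap: ",
         paste(overlap, collapse = ", "))
  proj <- as.character(dataset$meta$project_id)
  unassigned <- setdiff(unique(proj), c(train_projects, test_projects))
  if (length(unassigned) > 0L)
    warning("projects in neither split, their samples are dropped: ",
            paste(unassigned, collapse = ", "))
  list(train = subset_dataset(dataset, which(proj %in% train_projects)),
       test  = subset_dataset(dataset, which(proj %in% test_projects)))
}
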