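#' Read an individuals-by-markers matrix from TSV/CSV
#'
#' Expects a header row of marker ids with the individual id in the first
#' column. Genotype dosages must lie in \[0,2\]; methylation values are
#' auto-detected as beta values (all in \[0,1\]) or M-values (unbounded),
#' overridable via `values`.
#'
#' @param path file path (TSV or CSV; delimiter auto-detected).
#' @param kind `"methylation"` or `"genotype"`.
#' @param values for methylation: `"auto"`, `"beta"` or `"mvalue"`.
#' @return numeric matrix with individual ids as rownames and marker ids
#'   as colnames; attribute `values` records the detected value type.
#' @export
read_marker_matrix <- function(path, kind = c("methylation", "genotype"),
                               values = c("auto", "beta", "mvalue")) {
  kind <- match.arg(kind)
  values <- match.arg(values)
  warn_msg <- NULL                          # ragged/truncated files are fatal
  dt <- withCallingHandlers(
    data.table::fread(path, header = TRUE, data.table = FALSE, fill = FALSE),
    warning = function(w) {
      warn_msg <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    }
  )
  if (!is.null(warn_msg))
    stop("malformed matrix file ", path, ": ", warn_msg)
  ids <- as.character(dt[[1]])
  if (anyDuplicated(ids))
    stop("duplicate individual ids: ",
         paste(utils::head(unique(ids[duplicated(ids)]), 5), collapse = ", "))
  m <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (anyDuplicated(colnames(m))) stop("duplicate marker ids in header")
  check_range <- function(lo, hi, what) {
    bad <- which(m < lo | m > hi | is.na(m), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      msg <- apply(utils::head(bad, 10), 1, function(rc)
        sprintf("[%s, %s] = %s", ids[rc[1]], colnames(m)[rc[2]],
                format(m[rc[1], rc[2]])))
      stop(what, " out of range [", lo, ", ", hi, "] at: ",
           paste(msg, collapse = "; "))
    }
  }
  vtype <- "dosage"
  if (kind == "genotype") {
    check_range(0, 2, "genotype dosage")
  } else {
    vtype <- if (values == "auto") {
      if (all(m >= 0 & m <= 1, na.rm = TRUE)) "beta" else "mvalue"
    } else values
    if (vtype == "beta") check_range(0, 1, "methylation beta")
    else if (anyNA(m)) stop("missing methylation values")
  }
  attr(m, "values") <- vtype
  m
}

#' Write an individuals-by-markers matrix as TSV
#'
#' @param m numeric matrix with row and column names.
#' @param path output path.
#' @param id_column name of the leading individual-id column.
#' @export
write_marker_matrix <- function(m, path, id_column = "id") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read PLINK bed/bim/fam genotypes as a dosage matrix
#'
#' Decodes the PLINK 1 binary format (SNP-major, 2 bits per genotype) into
#' an individuals-by-SNPs dosage matrix counting the first (A1) allele.
#' Missing genotypes become `NA`.
#'
#' @param prefix path prefix; `prefix.bed`, `prefix.bim`, `prefix.fam`
#'   must exist.
#' @return dosage matrix (0/1/2/NA) with individual ids (fam IID) as
#'   rownames and SNP ids as colnames.
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("missing file: ", f)
  bim_dt <- data.table::fread(bim, header = FALSE, data.table = FALSE)
  fam_dt <- data.table::fread(fam, header = FALSE, data.table = FALSE)
  n <- nrow(fam_dt)
  p <- nrow(bim_dt)
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(bed, "raw", n = 3 + p * bytes_per_snp)
  if (length(raw) < 3 + p * bytes_per_snp) stop("truncated .bed file")
  if (!identical(as.integer(raw[1:2]), c(0x6cL, 0x1bL)))
    stop("not a PLINK .bed file (bad magic number)")
  if (as.integer(raw[3]) != 1L) stop("only SNP-major .bed files supported")
  body <- as.integer(raw[-(1:3)])
  # 2-bit codes, little-endian within byte: 00=hom A1 (2), 01=missing,
  # 10=het (1), 11=hom A2 (0)
  lookup <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)
  shifts <- c(1L, 4L, 16L, 64L)
  G <- matrix(NA_real_, n, p,
              dimnames = list(as.character(fam_dt[[2]]),
                              as.character(bim_dt[[2]])))
  for (j in seq_len(p)) {
    b <- body[((j - 1) * bytes_per_snp + 1):(j * bytes_per_snp)]
    codes <- as.vector(vapply(shifts,
                              function(s) (b %/% s) %% 4L,
                              integer(bytes_per_snp)))
    # vapply above groups by shift; interleave to individual order
    codes <- as.vector(t(matrix(codes, ncol = 4)))
    G[, j] <- lookup[codes[seq_len(n)] + 1L]
  }
  G
}

#' Read / write a marker weight file
#'
#' Two-column (id, weight) TSV with `#key: value` metadata header lines
#' carrying the training phenotype anchors; round-trips exactly through
#' [write_weights()].
#'
#' @param path file path.
#' @return a [weight_set()].
#' @export
read_weights <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    key <- sub(":.*$", "", kv)
    meta[[trimws(key)]] <- trimws(sub("^[^:]*:", "", kv))
  }
  dt <- data.table::fread(text = lines[!grepl("^#", lines)], header = TRUE,
                          data.table = FALSE)
  if (ncol(dt) < 2) stop("weight file needs id and weight columns")
  if (anyDuplicated(dt[[1]])) stop("duplicate marker ids in weight file")
  w <- stats::setNames(as.numeric(dt[[2]]), as.character(dt[[1]]))
  weight_set(w,
             train_pheno_mean = as.numeric(meta$train_pheno_mean %||% NA),
             train_pheno_sd = as.numeric(meta$train_pheno_sd %||% NA))
}

#' @rdname read_weights
#' @param ws a [weight_set()].
#' @export
write_weights <- function(ws, path) {
  stopifnot(inherits(ws, "weight_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#source: ", ws$source),
    paste0("#train_pheno_mean: ", format(ws$train_pheno_mean, digits = 17)),
    paste0("#train_pheno_sd: ", format(ws$train_pheno_sd, digits = 17)),
    "id\tweight",
    paste(ws$marker_ids, format(ws$weights, digits = 17, trim = TRUE,
                                scientific = FALSE), sep = "\t")
  ), con)
  invisible(path)
}

REPORT_SCHEMA_VERSION <- "1.0"

.serialize_result <- function(x) {
  if (inherits(x, "bayesr")) {
    list(type = "bayesr",
         var_frac = as.list(x$var_frac),
         cri95 = apply(x$cri95, 2, as.list),
         class_counts = as.data.frame(x$class_counts),
         class_var_share = as.data.frame(x$class_var_share),
         n_draws = x$n_draws, n = x$n,
         pip = lapply(x$pip, as.list))
  } else if (inherits(x, "oreml")) {
    list(type = "oreml",
         var_components = as.list(x$var_components),
         se = as.list(stats::setNames(x$se, names(x$var_components))),
         ci95 = apply(x$ci95, 2, as.list),
         loglik = x$loglik, converged = x$converged,
         n_iter_used = x$n_iter_used, n = x$n)
  } else if (inherits(x, "bivar_oreml")) {
    list(type = "bivar_oreml",
         var_frac_group1 = x$var_frac_group1,
         var_frac_group2 = x$var_frac_group2,
         r_corr = x$r_corr, se_r = x$se_r, p_r_eq_1 = x$p_r_eq_1)
  } else if (inherits(x, "score_report")) {
    list(type = "score_report",
         pearson_r = x$pearson_r, r_pvalue = x$r_pvalue,
         incremental_adj_r2 = x$incremental_adj_r2,
         score_pvalue = x$score_pvalue,
         decile_diff_cm = x$decile_diff_cm, decile_pvalue = x$decile_pvalue,
         n = x$n, n_markers_used = x$n_markers_used)
  } else if (inherits(x, "phewas_table")) {
    list(type = "phewas_table",
         alpha = attr(x, "alpha"), threshold = attr(x, "threshold"),
         skipped = attr(x, "skipped"),
         table = as.data.frame(x))
  } else if (is.list(x) && !is.data.frame(x)) {
    lapply(x, .serialize_result)
  } else if (is.data.frame(x) || is.atomic(x)) {
    x
  } else {
    stop("cannot serialize object of class ", paste(class(x), collapse = "/"))
  }
}

#' Write an analysis result as versioned JSON (plus TSV where tabular)
#'
#' Serializes fitted objects (`bayesr`, `oreml`, `bivar_oreml`,
#' `score_report`, `phewas_table`, or named lists thereof) to a JSON file
#' with a schema version field and deterministic key order; a
#' `phewas_table` additionally gets a TSV alongside.
#'
#' @param results object or named list of objects.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  payload <- list(schema_version = REPORT_SCHEMA_VERSION,
                  results = .serialize_result(results))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  if (inherits(results, "phewas_table")) {
    data.table::fwrite(as.data.frame(results),
                       sub("\\.json$", ".tsv", path), sep = "\t")
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(rep$schema_version)) stop("report lacks schema_version")
  rep
}

#' Write a synthetic cohort to a directory
#'
#' Emits `methylation.tsv`, `genotypes.tsv`, `covariates.tsv` (with the
#' phenotype as a `height_cm` column) and `truth.json`; the matrices
#' round-trip through [read_marker_matrix()].
#'
#' @param data a `cohort_data` object.
#' @param dir output directory (created if absent).
#' @param overwrite refuse to overwrite existing files unless `TRUE`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(data, dir, overwrite = FALSE) {
  stopifnot(inherits(data, "cohort_data"))
  if (length(data$ids) == 0) stop("refusing to write an empty cohort")
  files <- file.path(dir, c("methylation.tsv", "genotypes.tsv",
                            "covariates.tsv", "truth.json"))
  if (!overwrite && any(file.exists(files)))
    stop("output files exist; use overwrite = TRUE")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_marker_matrix(data$methylation, files[1])
  write_marker_matrix(data$genotypes, files[2])
  cov <- data$covariates
  cov$height_cm <- data$phenotype
  data.table::fwrite(cov, files[3], sep = "\t")
  truth <- data$truth
  truth$g_dnam <- NULL
  truth$g_snp <- NULL
  jsonlite::write_json(truth, files[4], auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  M <- read_marker_matrix(file.path(dir, "methylation.tsv"), "methylation")
  G <- read_marker_matrix(file.path(dir, "genotypes.tsv"), "genotype")
  cov <- data.table::fread(file.path(dir, "covariates.tsv"),
                           data.table = FALSE)
  cov$batch <- factor(cov$batch)
  cov$slide <- factor(cov$slide)
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path))
    jsonlite::read_json(truth_path, simplifyVector = TRUE) else NULL
  ids <- cov$id
  if (!identical(rownames(M), ids) || !identical(rownames(G), ids))
    stop("individual ids differ across cohort files")
  height <- cov$height_cm
  cov$height_cm <- NULL
  out <- list(genotypes = G, methylation = M, phenotype = height,
              covariates = cov, ids = ids, truth = truth, config = NULL)
  class(out) <- "cohort_data"
  out
}

#' Align data sets on shared individual ids
#'
#' @param ids_list list of character id vectors.
#' @param mode `"strict"` (error unless all identical) or `"intersect"`
#'   (keep the common ids, report how many were dropped).
#' @return character vector of aligned ids.
#' @export
align_ids <- function(ids_list, mode = c("strict", "intersect")) {
  mode <- match.arg(mode)
  if (mode == "strict") {
    for (i in seq_along(ids_list)[-1]) {
      if (!identical(ids_list[[1]], ids_list[[i]]))
        stop("individual ids do not match across inputs (strict mode)")
    }
    return(ids_list[[1]])
  }
  common <- Reduce(intersect, ids_list)
  dropped <- sum(vapply(ids_list, function(x) length(setdiff(x, common)),
                        numeric(1)))
  if (dropped > 0)
    message(dropped, " id(s) dropped during intersection alignment")
  common
}
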