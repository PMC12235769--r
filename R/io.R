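# Readers and writers for the supported plain-text formats. All writes are
# atomic (write to a temporary file in the target directory, then rename).

atomic_write <- function(path, writer) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move temporary file onto ", path)
  invisible(path)
}

guess_sep <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else ","
}

#' Read a genotype dosage table
#'
#' Reads SNP dosages coded 0/1/2, one row per individual with an ID column
#' and a header of marker names. Supported dialects: `csv`, `tsv` and
#' `plink_raw` (PLINK `--recode A` output, whose leading FID/IID/PAT/MAT/
#' SEX/PHENOTYPE metadata columns are skipped, IID becoming the ID).
#' Missing genotypes may be encoded as `NA` or `-9`; any other value
#' outside {0, 1, 2} is a parse error reporting the offending cell.
#'
#' @param path file path.
#' @param dialect `"csv"`, `"tsv"` or `"plink_raw"`; `NULL` guesses csv/tsv
#'   from the header line.
#' @return integer dosage matrix with individual IDs as rownames; missing
#'   entries are `NA`.
#' @export
read_genotypes <- function(path, dialect = NULL) {
  if (is.null(dialect)) dialect <- if (guess_sep(path) == "\t") "tsv" else "csv"
  dialect <- match.arg(dialect, c("csv", "tsv", "plink_raw"))
  sep <- if (dialect == "csv") "," else if (dialect == "tsv") "\t" else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "plink_raw") {
    meta <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"), names(df))
    ids <- as.character(df[["IID"]])
    df <- df[, setdiff(names(df), meta), drop = FALSE]
  } else {
    ids <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
  }
  M <- as.matrix(df)
  suppressWarnings(storage.mode(M) <- "double")
  M[which(M == -9)] <- NA
  bad <- which(!is.na(M) & !(M %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("invalid genotype value '%s' at row %d, column '%s' of %s",
                 M[bad[1, 1], bad[1, 2]], bad[1, 1],
                 colnames(M)[bad[1, 2]], path))
  }
  rownames(M) <- ids
  M
}

#' Write a genotype dosage table
#'
#' @param M dosage matrix with individual IDs as rownames.
#' @param path output path (comma-separated, ID column `id`).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(M, path) {
  df <- data.frame(id = rownames(M), M, check.names = FALSE)
  atomic_write(path, function(f)
    utils::write.table(df, f, sep = ",", quote = FALSE, row.names = FALSE))
  invisible(path)
}

#' Read a phenotype table
#'
#' One row per individual: an ID column followed by one numeric column per
#' trait; `NA` marks missing phenotypes.
#'
#' @param path file path (csv or tsv, guessed from the header).
#' @return numeric matrix with individual IDs as rownames.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = guess_sep(path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  Y <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(Y) <- "double"
  rownames(Y) <- ids
  Y
}

#' Write a phenotype table
#'
#' @param Y trait matrix with individual IDs as rownames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(Y, path) {
  df <- data.frame(id = rownames(Y), Y, check.names = FALSE)
  atomic_write(path, function(f)
    utils::write.table(df, f, sep = ",", quote = FALSE, row.names = FALSE))
  invisible(path)
}

#' Write / read a relationship matrix
#'
#' CSV with the individual IDs both as header row and as the first column.
#'
#' @param A relationship matrix with ID dimnames.
#' @param path file path.
#' @return `path` invisibly (write); the matrix (read).
#' @export
write_relationship <- function(A, path) {
  df <- data.frame(id = rownames(A), A, check.names = FALSE)
  atomic_write(path, function(f)
    utils::write.table(df, f, sep = ",", quote = FALSE, row.names = FALSE))
  invisible(path)
}

#' @rdname write_relationship
#' @export
read_relationship <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = ",", check.names = FALSE)
  A <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(A) <- "double"
  rownames(A) <- as.character(df[[1]])
  A
}

#' Write a loadings matrix
#'
#' CSV keyed by individual ID with columns `PC1..PCm`.
#'
#' @param L loadings matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_loadings <- function(L, path) {
  df <- data.frame(id = rownames(L), L, check.names = FALSE)
  atomic_write(path, function(f)
    utils::write.table(df, f, sep = ",", quote = FALSE, row.names = FALSE))
  invisible(path)
}

#' Align genotype, phenotype and loadings tables by individual ID
#'
#' Inner-joins the inputs on their row IDs (sorted ID order) and reports
#' how many individuals were dropped from each source. Missing genotype
#' dosages are mean-imputed per marker column (logged), since downstream
#' standardization requires complete features.
#'
#' @param genotypes dosage matrix with ID rownames (or `NULL`).
#' @param phenotypes trait matrix with ID rownames.
#' @param loadings optional loadings matrix with ID rownames.
#' @param quiet suppress the drop/imputation messages.
#' @return list with aligned `features` (joint matrix with provenance),
#'   `genotypes`, `loadings`, `y` and `ids`.
#' @export
align_data <- function(genotypes = NULL, phenotypes, loadings = NULL,
                       quiet = FALSE) {
  sets <- list(genotypes = rownames(genotypes), phenotypes = rownames(phenotypes),
               loadings = rownames(loadings))
  sets <- sets[!vapply(sets, is.null, TRUE)]
  ids <- sort(Reduce(intersect, sets))
  if (!length(ids)) stop("no individuals shared between the input tables")
  if (!quiet) {
    for (nm in names(sets)) {
      dropped <- length(sets[[nm]]) - length(ids)
      if (dropped > 0) message(dropped, " individual(s) dropped from ", nm)
    }
  }
  G <- if (!is.null(genotypes)) genotypes[ids, , drop = FALSE]
  if (!is.null(G) && anyNA(G)) {
    nmiss <- sum(is.na(G))
    for (j in seq_len(ncol(G))) {
      miss <- is.na(G[, j])
      if (any(miss)) G[miss, j] <- mean(G[, j], na.rm = TRUE)
    }
    if (!quiet) message(nmiss, " missing genotype value(s) mean-imputed")
  }
  L <- if (!is.null(loadings)) loadings[ids, , drop = FALSE]
  X <- assemble_features(markers = G, loadings = L)
  rownames(X) <- ids
  list(features = X, genotypes = G, loadings = L,
       y = phenotypes[ids, , drop = FALSE], ids = ids)
}
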