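#' @keywords internal
"_PACKAGE"

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

TRUNCATING_CLASSES <- c("nonsense", "frameshift", "splice")
CONSEQUENCE_CLASSES <- c("missense", "nonsense", "frameshift", "splice",
                         "silent", "other")
REGION_CLASSES <- c("promoter_2kb", "gene_body", "first_intron")

# Run expr under a locally seeded RNG stream, restoring the caller's RNG
# state afterwards. Sub-stream seeds are derived from (seed, offset) and kept
# below 2^31 so they are valid R integer seeds.
with_substream <- function(seed, offset, expr) {
  sub <- (as.numeric(seed) %% 1000003) * 2011 + offset * 100003
  sub <- as.integer(sub %% 2147483647)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(sub)
  expr
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg),
       call. = FALSE)
}

#' Read a tab-separated table
#'
#' Thin wrapper around [utils::read.delim()] fixing the conventions used by
#' every file in a cohort directory: tab separator, header row, no
#' string-to-factor coercion, no name munging.
#'
#' @param path File path.
#' @return A `data.frame`.
#' @export
read_tsv_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write a tab-separated table
#'
#' Deterministic TSV writer (fixed 15-significant-digit numeric formatting)
#' so that identical inputs always produce byte-identical files.
#'
#' @param df A `data.frame`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tsv_file <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- vapply(out[[j]], function(v) {
        if (is.na(v)) "NA" else format(v, digits = 15, scientific = FALSE,
                                       trim = TRUE)
      }, character(1))
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# genes/probes x samples numeric matrix <-> TSV with an id first column
write_matrix_tsv <- function(mat, path, id_col = "gene") {
  df <- data.frame(id = rownames(mat), as.data.frame(mat, check.names = FALSE),
                   check.names = FALSE)
  names(df)[1] <- id_col
  write_tsv_file(df, path)
}

read_matrix_tsv <- function(path, id_col = "gene") {
  df <- read_tsv_file(path)
  if (names(df)[1] != id_col)
    stop(sprintf("expected first column '%s' in %s, found '%s'",
                 id_col, path, names(df)[1]), call. = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicated row ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  mat
}

# Vectorised two-sample t-test over matrix rows.
# X: features x samples; idx1/idx2: column indices for the two groups.
# var_equal = TRUE gives the classical Student test (pooled variance);
# FALSE gives Welch. Rows where either group variance is zero (or a group
# has < 2 samples) get p = NA: degenerate, not evaluable.
row_t_test <- function(X, idx1, idx2, var_equal = TRUE) {
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(X[, idx1, drop = FALSE])
  m2 <- rowMeans(X[, idx2, drop = FALSE])
  v1 <- apply(X[, idx1, drop = FALSE], 1, stats::var)
  v2 <- apply(X[, idx2, drop = FALSE], 1, stats::var)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  bad <- n1 < 2 | n2 < 2 | !is.finite(se) | se == 0
  p[bad] <- NA_real_
  tstat[bad] <- NA_real_
  list(mean1 = m1, mean2 = m2, t = tstat, p = p, df = df)
}

# Row-wise Pearson correlation between matched rows of X and Y
# (features x samples), with the usual t-distributed two-sided p.
row_pearson <- function(X, Y) {
  n <- ncol(X)
  cx <- X - rowMeans(X)
  cy <- Y - rowMeans(Y)
  sx <- sqrt(rowSums(cx^2))
  sy <- sqrt(rowSums(cy^2))
  r <- rowSums(cx * cy) / (sx * sy)
  r[sx == 0 | sy == 0] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  p[is.na(r)] <- NA_real_
  if (n < 3) { r[] <- NA_real_; p[] <- NA_real_ }
  list(r = r, p = p, n = n)
}
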