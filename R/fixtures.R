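#' Random symmetric Hamiltonian with a prescribed spectrum
#'
#' Builds \eqn{H = U^T \Lambda U} with `U` a seeded random orthogonal matrix
#' (QR of a standard normal matrix, sign-fixed so the factorization is
#' unique), so the eigenvalues of the result equal `eigenvalues` to machine
#' precision. The global RNG state is left untouched.
#'
#' @param eigenvalues Numeric vector (length >= 2) of prescribed eigenvalues
#'   (hartree).
#' @param seed Integer seed; identical seeds give identical matrices.
#' @return A real symmetric matrix of dimension `length(eigenvalues)`.
#' @examples
#' H <- random_hamiltonian(c(0, 1, 2), seed = 1)
#' eigen(H, symmetric = TRUE)$values
#' @export
random_hamiltonian <- function(eigenvalues, seed) {
  eigenvalues <- as.numeric(eigenvalues)
  n <- length(eigenvalues)
  if (n < 2 || any(!is.finite(eigenvalues))) {
    stop("`eigenvalues` must be >= 2 finite values", call. = FALSE)
  }
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    stop("a single integer `seed` is required", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  A <- matrix(stats::rnorm(n * n), n, n)
  qr_ <- qr(A)
  U <- qr.Q(qr_)
  U <- U %*% diag(sign(diag(qr.R(qr_))), n)   # unique Q for reproducibility
  M <- U %*% diag(eigenvalues, n) %*% t(U)
  (M + t(M)) / 2
}

#' Export / import result tables with a reproducibility header
#'
#' Writes a data frame of numeric results as CSV or JSON with a header
#' carrying the package version, the seed and a configuration string, and
#' reads it back losslessly: numeric fields are serialized at full double
#' precision so a round trip reproduces bit-identical values.
#'
#' @param records A `data.frame` (may have zero rows).
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @param seed Optional integer recorded in the header.
#' @param config Optional named list or string recorded in the header.
#' @return `export_table()` returns `path` invisibly; `import_table()`
#'   returns a list with `records` (data.frame) and `header` (list).
#' @export
export_table <- function(records, path, format = c("csv", "json"),
                         seed = NULL, config = NULL) {
  format <- match.arg(format)
  stopifnot(is.data.frame(records))
  header <- list(
    package = "statescape",
    version = as.character(utils::packageVersion("statescape")),
    seed = seed,
    config = if (is.list(config)) paste(names(config), unlist(config),
                                        sep = "=", collapse = ";") else config
  )
  if (format == "json") {
    jsonlite::write_json(list(header = header, records = records), path,
                         auto_unbox = TRUE, digits = I(17), null = "null",
                         dataframe = "rows")
  } else {
    hdr <- sprintf("# %s: %s", names(header),
                   vapply(header, function(v) if (is.null(v)) "NA" else as.character(v), ""))
    txt <- vapply(records, function(col) {
      if (is.double(col)) sprintf("%.17g", col) else as.character(col)
    }, character(nrow(records)))
    if (nrow(records) == 1L) txt <- matrix(txt, nrow = 1)
    body <- c(paste(names(records), collapse = ","),
              if (nrow(records) > 0) apply(as.matrix(txt), 1, paste, collapse = ","))
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}

#' @rdname export_table
#' @export
import_table <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    rec <- obj$records
    if (is.null(rec) || length(rec) == 0) rec <- data.frame()
    return(list(records = as.data.frame(rec), header = as.list(obj$header)))
  }
  lines <- readLines(path)
  is_hdr <- grepl("^#", lines)
  header <- list()
  for (h in lines[is_hdr]) {
    kv <- sub("^#\\s*", "", h)
    key <- sub(":.*$", "", kv)
    header[[key]] <- trimws(sub("^[^:]*:", "", kv))
  }
  body <- lines[!is_hdr]
  if (length(body) <= 1L) {
    cols <- if (length(body) == 1L) strsplit(body[1], ",")[[1]] else character()
    rec <- as.data.frame(matrix(nrow = 0, ncol = length(cols),
                                dimnames = list(NULL, cols)))
    return(list(records = rec, header = header))
  }
  rec <- utils::read.csv(text = paste(body, collapse = "\n"),
                         stringsAsFactors = FALSE)
  list(records = rec, header = header)
}
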