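# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals never perturb the
#' caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  env <- globalenv()
  has_seed <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = env)
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(expr)
}

#' Coerce any Matrix sparse form to general column-compressed
#' @noRd
as_dgc <- function(m) {
  if (is.matrix(m)) m <- Matrix::Matrix(m, sparse = TRUE)
  methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Locate the bundled python helper scripts
#' @noRd
py_script <- function(name) {
  p <- system.file("python", name, package = "umiqc")
  if (!nzchar(p)) stopf("bundled python helper '%s' not found", name)
  p
}

#' Run a bundled python helper, error on failure
#' @noRd
run_python <- function(script, args) {
  out <- suppressWarnings(system2("python", c(shQuote(script), shQuote(args)),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stopf("python helper failed (%s):\n%s", basename(script),
          paste(out, collapse = "\n"))
  }
  invisible(out)
}

# full-precision numeric formatting for lossless text round-trips
fmt_full <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}
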