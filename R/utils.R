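#' @useDynLib neuroarbor, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd aov anova t.test wilcox.test setNames
#' @importFrom utils head tail read.table write.table read.csv write.csv
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# seed = NULL draws from the current stream (generator still reproducible
# if the caller seeded it).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      stats::runif(1)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

stopf <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cond <- structure(class = c(class, "neuroarbor_error", "error", "condition"),
                    list(message = msg, call = sys.call(-1)))
  stop(cond)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stopf("parameter_error", "`%s` must be a single finite number", name)
  }
  if (x < lower || x > upper || (strict_lower && x <= lower)) {
    stopf("parameter_error", "`%s` = %g outside allowed range", name, x)
  }
  invisible(x)
}

# unit vector
vnorm <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero-length vector")
  v / n
}

# Rodrigues rotation of v by angle (radians) about unit axis a
rotate_about <- function(v, a, angle) {
  a <- vnorm(a)
  v * cos(angle) + pracma_cross(a, v) * sin(angle) +
    a * sum(a * v) * (1 - cos(angle))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# any unit vector perpendicular to d
perp_vector <- function(d) {
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  vnorm(pracma_cross(d, ref))
}
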