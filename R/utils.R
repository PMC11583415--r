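#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor median sd pwilcox pnorm pt phyper p.adjust t.test
#'   aov TukeyHSD prop.test pchisq rnorm runif rbeta rexp rbinom rlnorm
#'   fisher.test setNames as.dist cutree hclust
#' @importFrom utils read.csv write.csv read.delim write.table head
#'   packageVersion
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

# Set the RNG state locally (restored on exit) when a seed is supplied.
with_local_seed <- function(seed, envir = parent.frame()) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    withr::local_seed(as.integer(seed), .local_envir = envir)
  }
  invisible(NULL)
}

# Derive a reproducible per-stage seed from a master seed so that adding a
# stage never perturbs the randomness consumed by earlier stages.
derive_seed <- function(master, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
  as.integer((as.numeric(master) * 48271 + h) %% 2147483647)
}

assert_flag <- function(x, name = deparse(substitute(x))) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be TRUE or FALSE", name), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name = deparse(substitute(x)), min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop(sprintf("'%s' must be a single integer >= %s", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

assert_number <- function(x, name = deparse(substitute(x)),
                          lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(as.numeric(x))
}
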