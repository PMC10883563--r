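# internal helpers shared across modules

# package-level verbosity: 0 silent, 1 info, 2 debug; messages go to stderr
.gma_env <- new.env(parent = emptyenv())
.gma_env$verbosity <- 0L

#' Set package verbosity
#'
#' @param level 0 (silent), 1 (info) or 2 (debug); messages are emitted on
#'   stderr via [message()].
#' @return The previous level, invisibly.
#' @export
gma_verbosity <- function(level = 1L) {
  old <- .gma_env$verbosity
  .gma_env$verbosity <- as.integer(level)
  invisible(old)
}

.log <- function(..., level = 1L) {
  if (.gma_env$verbosity >= level) message("[gmascreen] ", ...)
  invisible(NULL)
}

# run `expr` under a locally-seeded RNG without disturbing the caller's stream;
# seed = NULL uses (and advances) the global stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# band-limited Gaussian noise via FFT masking: length n at sampling rate fs,
# passband [f_lo, f_hi] Hz, scaled to standard deviation `sd`
band_noise <- function(n, fs, f_lo, f_hi, sd = 1) {
  if (n < 4 || sd == 0) return(numeric(n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  freq <- (seq_len(n) - 1) / n * fs
  freq <- pmin(freq, fs - freq)              # two-sided spectrum
  keep <- freq >= f_lo & freq <= f_hi
  W[!keep] <- 0
  out <- Re(stats::fft(W, inverse = TRUE)) / n
  s <- stats::sd(out)
  if (s < .Machine$double.eps) return(numeric(n))
  out / s * sd
}

# smooth low-frequency noise: cumulative random walk low-passed below f_hi
slow_noise <- function(n, fs, f_hi, sd = 1) band_noise(n, fs, 0, f_hi, sd)

# 2D rotation matrix for image coordinates (y down); rotates column vectors
rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

# read a YAML/JSON-semantics config file into a named list
#' Read a configuration file
#'
#' One structured-text (YAML) schema is shared by the CLI commands and can
#' override the defaults of [synth_config()], [preprocess_config()] and
#' [gma_control()]: top-level keys `simulate`, `preprocess`, `model` each hold
#' a mapping of argument overrides.
#'
#' @param path Path to a YAML file.
#' @return Named list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

# merge user overrides into a default list, erroring on unknown keys
merge_config <- function(defaults, overrides, what = "config") {
  if (is.null(overrides)) return(defaults)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("unknown ", what, " option(s): ", paste(unknown, collapse = ", "))
  defaults[names(overrides)] <- overrides
  defaults
}
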