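`%||%` <- function(a, b) if (is.null(a)) b else a

# Read a JSON or YAML config file by extension.
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop(sprintf("unsupported config format '.%s' (use .json or .yaml)", ext),
         call. = FALSE)
  }
}

# First-order low-pass: y[k] = a*y[k-1] + (1-a)*u[k], y[0] = init.
lowpass1 <- function(u, a, init = u[1]) {
  as.numeric(stats::filter((1 - a) * u, a, method = "recursive", init = init))
}

# Sample-wise skewness (biased moment estimator; only used descriptively).
skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^3) / s2^1.5
}
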