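# Internal helpers: seeded evaluation and provenance headers.

# Evaluate `expr` under a temporary RNG state seeded with `seed`;
# the caller's .Random.seed is restored afterwards. seed = NULL leaves
# the global stream untouched (advancing it).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop(sprintf("'%s' must be an integer >= %s", name, format(min)))
  as.numeric(x)
}

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single number", name))
  if (x < min || (strict_min && x <= min) || x > max)
    stop(sprintf("'%s' out of range", name))
  as.numeric(x)
}

# FNV-1a over the deparsed object; provenance fingerprint for file headers.
config_fingerprint <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    # 32-bit arithmetic kept exact in doubles by splitting into 16-bit halves
    lo <- bitwXor(h %% 65536, b %% 65536)
    h <- (h %/% 65536) * 65536 + lo
    h <- ((h %% 65536) * prime + (((h %/% 65536) * prime) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

provenance_header <- function(seed = NULL, config = NULL, extra = character()) {
  ver <- as.character(utils::packageVersion("resectquant"))
  lines <- sprintf("# resectquant version=%s", ver)
  if (!is.null(seed)) lines <- c(lines, sprintf("# seed=%d", as.integer(seed)))
  if (!is.null(config))
    lines <- c(lines, sprintf("# config_fingerprint=%s", config_fingerprint(config)))
  c(lines, extra)
}
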