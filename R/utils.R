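#' @keywords internal
#' @useDynLib rsnmap, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Default network names for the 13 canonical resting-state networks; phantoms
# with K < 13 take the first K, larger K append NET14, NET15, ...
RSN_NAMES <- c("SMD", "SML", "CON", "AUD", "DMN", "PMN", "VIS",
               "FPN", "SAL", "VAN", "DAN", "MTL", "REW")

default_network_names <- function(k) {
  stopifnot(k >= 1)
  if (k <= length(RSN_NAMES)) return(RSN_NAMES[seq_len(k)])
  c(RSN_NAMES, paste0("NET", seq(length(RSN_NAMES) + 1L, k)))
}

# Deterministic substream seed: a master seed plus a named stage offset.
# Keeps results reproducible when unrelated stages change their random draws.
# Result is always a valid 32-bit integer seed.
substream_seed <- function(master, name) {
  h <- sum(utf8ToInt(as.character(name)) * seq_along(utf8ToInt(as.character(name))))
  as.integer((as.numeric(master) * 48271 + h * 16807) %% 2147483587) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# linear index <-> (i,j,k) for a 3D grid, 1-based
vox_index <- function(ijk, dim) {
  as.integer((ijk[, 3] - 1L) * dim[1] * dim[2] + (ijk[, 2] - 1L) * dim[1] + ijk[, 1])
}

vox_coords <- function(idx, dim) {
  idx0 <- idx - 1L
  i <- idx0 %% dim[1]
  j <- (idx0 %/% dim[1]) %% dim[2]
  k <- idx0 %/% (dim[1] * dim[2])
  cbind(i + 1L, j + 1L, k + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_rsn <- function(cls, fmt, ...) {
  stop(structure(class = c(cls, "rsnmap_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}
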