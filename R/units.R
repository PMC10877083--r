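#' @keywords internal
#' @useDynLib nanocorona, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

## Physical constants (SI) and unit helpers. Internal convention everywhere
## else in the package: lengths nm, energies kBT, charges e, concentrations
## mol/L, times s. Conversions to SI happen only inside rate formulas.

.kB <- 1.380649e-23           # J/K
.NA <- 6.02214076e23          # 1/mol
.e_charge <- 1.602176634e-19  # C
.nm <- 1e-9                   # m

.deg2rad <- function(x) x * pi / 180

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## FNV-1a 32-bit hash of character input; stamps run manifests so reruns are
## auditable without an external digest dependency. The 2^32 modular multiply
## is done with a 16-bit split so intermediates stay below 2^53.
.fnv1a <- function(s) {
  bytes <- utf8ToInt(enc2utf8(paste(s, collapse = "\n")))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo <- h %% 256  # XOR with a byte only touches the low 8 bits
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (h0 * p + ((h1 * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%08x", h)
}
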