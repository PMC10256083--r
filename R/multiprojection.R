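# Multiprojection of cepstral matrices: each mapping sends every
# coefficient trajectory (a row, one point of R^nframes) to a scalar, so a
# cepstral matrix projects to a length-nceps vector. Concatenating the
# projections of the static, delta and delta-delta matrices over an ordered
# mapping set gives the compact per-technique representation, and
# concatenating over an ordered technique set gives the fused cepstral
# vector of length nP * 3 * nceps * nM.

MAPPING_NAMES <- c("PCA", "SUM", "STD", "SKEW")

# Named mapping-set presets (ordered).
MAPPING_SETS <- list(
  M1 = "PCA", M2 = "SUM", M3 = "STD", M4 = "SKEW",
  M5 = c("PCA", "SUM"), M6 = c("SUM", "STD"), M7 = c("STD", "SKEW"),
  M8 = c("SUM", "STD", "SKEW"), M9 = c("PCA", "SUM", "STD", "SKEW")
)

# Named technique-set presets (ordered).
TECHNIQUE_SETS <- list(
  P1 = "CQCC", P2 = "MFCC", P3 = "iMFCC", P4 = "BFCC", P5 = "LFCC",
  P6 = "LPCC", P7 = "GFCC", P8 = "NGCC",
  P9 = c("CQCC", "MFCC"), P10 = c("CQCC", "BFCC"), P11 = c("CQCC", "LFCC"),
  P12 = c("MFCC", "BFCC"), P13 = c("MFCC", "LFCC"),
  P14 = c("CQCC", "MFCC", "LFCC"), P15 = c("CQCC", "MFCC", "BFCC")
)

#' Ordered set of mapping functions
#'
#' @param names Character vector of mapping names from `"PCA"`, `"SUM"`,
#'   `"STD"`, `"SKEW"` (order defines the concatenation layout), or a
#'   preset alias `"M1"`..`"M9"`.
#' @return Character vector of class `mapping_set`.
#' @export
mapping_set <- function(names) {
  if (length(names) == 1L && names %in% base::names(MAPPING_SETS))
    names <- MAPPING_SETS[[names]]
  names <- as.character(names)
  if (length(names) == 0L) stop("mapping set must be non-empty")
  if (anyDuplicated(names)) stop("mapping set must not contain duplicates")
  if (!all(names %in% MAPPING_NAMES))
    stop("unknown mapping(s): ",
         paste(setdiff(names, MAPPING_NAMES), collapse = ", "))
  structure(names, class = "mapping_set")
}

#' Ordered set of cepstral techniques
#'
#' @param names Character vector of technique names (see [extract_cc()]) or
#'   a preset alias `"P1"`..`"P15"`.
#' @return Character vector of class `technique_set`.
#' @export
technique_set <- function(names) {
  if (length(names) == 1L && names %in% base::names(TECHNIQUE_SETS))
    names <- TECHNIQUE_SETS[[names]]
  names <- as.character(names)
  if (length(names) == 0L) stop("technique set must be non-empty")
  if (anyDuplicated(names)) stop("technique set must not contain duplicates")
  if (!all(names %in% CC_TECHNIQUES))
    stop("unknown technique(s): ",
         paste(setdiff(names, CC_TECHNIQUES), collapse = ", "))
  structure(names, class = "technique_set")
}

#' Project a cepstral matrix to one scalar per coefficient
#'
#' `SUM`: row sums. `STD`: row population standard deviations. `SKEW`: row
#' skewness `g1 = m3 / m2^(3/2)` of central moments across frames (0 when
#' the row variance is negligible). `PCA`: the rows are treated as nceps
#' samples in frame space, centred by their mean row, and each row's score
#' on the first principal axis (leading right singular vector) is returned;
#' the axis sign is fixed so its largest-magnitude entry is positive.
#'
#' Matrices with a single frame are degenerate: `STD`, `SKEW` and `PCA`
#' return zeros and `SUM` returns the single column.
#'
#' @param mat Cepstral matrix (coefficients x frames).
#' @param name Mapping name: `"PCA"`, `"SUM"`, `"STD"` or `"SKEW"`.
#' @return Numeric vector of length `nrow(mat)`.
#' @export
apply_mapping <- function(mat, name) {
  name <- match.arg(name, MAPPING_NAMES)
  nf <- ncol(mat)
  if (nf == 1L && name != "SUM") return(numeric(nrow(mat)))
  switch(name,
    SUM = rowSums(mat),
    STD = {
      ctr <- mat - rowMeans(mat)
      sqrt(rowMeans(ctr^2))
    },
    SKEW = {
      ctr <- mat - rowMeans(mat)
      m2 <- rowMeans(ctr^2)
      m3 <- rowMeans(ctr^3)
      ifelse(m2 < 1e-12, 0, m3 / m2^1.5)
    },
    PCA = {
      ctr <- sweep(mat, 2L, colMeans(mat))
      sv <- svd(ctr, nu = 0, nv = 1L)
      v <- sv$v[, 1L]
      if (v[which.max(abs(v))] < 0) v <- -v
      drop(ctr %*% v)
    }
  )
}

#' Multiprojection of a cepstral set
#'
#' Concatenates, for each mapping in order, the projections of the static,
#' delta and delta-delta matrices, giving a vector of length
#' `3 * nceps * nM`.
#'
#' @param cc A `cepstral_set` from [extract_cc()] (or any list with
#'   matrices `C`, `D1`, `D2` of identical shape).
#' @param mappings A [mapping_set()] (or names coercible to one).
#' @return Named numeric vector of length `3 * nceps * nM`.
#' @export
multiproject <- function(cc, mappings) {
  mappings <- mapping_set(mappings)
  stopifnot(all(dim(cc$C) == dim(cc$D1)), all(dim(cc$C) == dim(cc$D2)))
  blocks <- lapply(mappings, function(m) {
    v <- c(apply_mapping(cc$C, m), apply_mapping(cc$D1, m),
           apply_mapping(cc$D2, m))
    names(v) <- paste(m, rep(c("C", "D1", "D2"), each = nrow(cc$C)),
                      rep(seq_len(nrow(cc$C)), 3L), sep = ".")
    v
  })
  unlist(blocks, use.names = TRUE)
}

#' Fused multiprojected cepstral vector
#'
#' Extracts a cepstral set for every technique in order, multiprojects each
#' with the mapping set, and concatenates, yielding a vector of length
#' `nP * 3 * nceps * nM`.
#'
#' @param signal A [voice_signal()].
#' @param techniques A [technique_set()] (or names/alias coercible to one).
#' @param mappings A [mapping_set()] (or names/alias coercible to one).
#' @param nceps Number of cepstral coefficients per technique (default 20).
#' @param ... Further arguments passed to [extract_cc()].
#' @return Named numeric vector of length `nP * 3 * nceps * nM`.
#' @export
fuse_cepstral <- function(signal, techniques, mappings, nceps = 20, ...) {
  techniques <- technique_set(techniques)
  mappings <- mapping_set(mappings)
  blocks <- lapply(techniques, function(tech) {
    v <- multiproject(extract_cc(signal, tech, nceps = nceps, ...), mappings)
    names(v) <- paste(tech, names(v), sep = ".")
    v
  })
  unlist(blocks, use.names = TRUE)
}
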