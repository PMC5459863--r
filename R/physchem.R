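# Average residue masses (Da), ExPASy values; water added once per chain.
AA_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
             C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
             H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
             M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
             T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.01524

# Kyte-Doolittle hydropathy scale
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

# EMBOSS-style pKa constants used for isoelectric point
PKA_EMBOSS <- c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
                H = 6.5, K = 10.8, R = 12.5, Y = 10.1)

#' Protein molecular weight
#'
#' Sum of average residue masses plus one water, in kilodaltons. `X` residues
#' take the mean of the 20 canonical residue masses and flag the result as
#' approximate (attribute `approximate`).
#'
#' @param sequence Amino-acid string (20 canonical letters plus `X`).
#' @return Mass in kDa; attribute `approximate` is `TRUE` when `X` was present.
#' @export
compute_mw <- function(sequence) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  if (length(aa) == 0L) stop("empty sequence")
  bad <- setdiff(aa, c(names(AA_MASS), "X"))
  if (length(bad)) stop("unknown residue(s): ", paste(unique(bad), collapse = ", "))
  masses <- AA_MASS[aa]
  masses[aa == "X"] <- mean(AA_MASS)
  out <- (sum(masses) + WATER_MASS) / 1000
  attr(out, "approximate") <- any(aa == "X")
  out
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over the termini and ionizable side chains
#' (C, D, E, H, K, R, Y) with the pKa set used by [compute_pi()].
#'
#' @param sequence Amino-acid string.
#' @param ph pH value.
#' @param pka Named pKa vector (default EMBOSS-style constants).
#' @return Net charge (positive minus negative).
#' @export
net_charge <- function(sequence, ph, pka = PKA_EMBOSS) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  n <- c(table(aa))
  cnt <- function(x) if (x %in% names(n)) n[[x]] else 0
  pos <- 1 / (1 + 10^(ph - pka["Nterm"])) +
    cnt("H") / (1 + 10^(ph - pka["H"])) +
    cnt("K") / (1 + 10^(ph - pka["K"])) +
    cnt("R") / (1 + 10^(ph - pka["R"]))
  neg <- 1 / (1 + 10^(pka["Cterm"] - ph)) +
    cnt("D") / (1 + 10^(pka["D"] - ph)) +
    cnt("E") / (1 + 10^(pka["E"] - ph)) +
    cnt("C") / (1 + 10^(pka["C"] - ph)) +
    cnt("Y") / (1 + 10^(pka["Y"] - ph))
  unname(pos - neg)
}

#' Isoelectric point by bisection
#'
#' Finds the pH at which the net charge crosses zero. The charge function is
#' monotone decreasing in pH, so bisection on (0, 14) converges; tolerance is
#' 0.01 pH units in at most 60 iterations. The pKa set used is recorded in the
#' `pka` attribute of the result.
#'
#' @inheritParams net_charge
#' @param tol Convergence tolerance on pH (default 0.01).
#' @return pI as a pH value with attribute `pka`.
#' @export
compute_pi <- function(sequence, pka = PKA_EMBOSS, tol = 0.01) {
  if (!nzchar(sequence)) stop("empty sequence")
  lo <- 0; hi <- 14
  for (iter in seq_len(60)) {
    mid <- (lo + hi) / 2
    if (net_charge(sequence, mid, pka) > 0) lo <- mid else hi <- mid
    # stop only once both the pH bracket and the residual charge are small
    if (hi - lo < tol &&
        abs(net_charge(sequence, (lo + hi) / 2, pka)) < 0.01) break
  }
  out <- (lo + hi) / 2
  attr(out, "pka") <- pka
  out
}

#' Predict transmembrane segments from hydropathy
#'
#' Kyte-Doolittle sliding-window scanner: residues whose centered window mean
#' is at least `threshold` form candidate runs; runs separated by fewer than
#' `merge_gap` residues are merged, and merged runs shorter than `min_len`
#' residues are discarded. `X` residues are excluded from window means (the
#' mean is taken over defined residues only), and windows are truncated at
#' the termini so that membrane helices abutting a sequence end remain
#' detectable.
#'
#' @param sequence Amino-acid string.
#' @param window Odd window width (default 19).
#' @param threshold Minimum window-mean hydropathy to call a residue
#'   membrane-like (default 1.6).
#' @param min_len Minimum segment length in residues (default 15).
#' @param merge_gap Runs separated by fewer than this many residues are merged
#'   (default 3).
#' @return data.frame with columns `start`, `end`, `mean_hydropathy` (mean of
#'   the qualifying residues' window scores); zero rows when none found. A
#'   sequence shorter than `window` yields zero rows with a warning.
#' @export
predict_tm_segments <- function(sequence, window = 19, threshold = 1.6,
                                min_len = 15, merge_gap = 3) {
  stopifnot(window %% 2 == 1)
  aa <- strsplit(toupper(sequence), "")[[1]]
  n <- length(aa)
  empty <- data.frame(start = integer(0), end = integer(0),
                      mean_hydropathy = numeric(0))
  if (n < window) {
    warning("sequence shorter than window (", n, " < ", window, ")")
    return(empty)
  }
  h <- KD_SCALE[aa]  # X and unknowns -> NA, excluded from window means
  half <- (window - 1L) / 2L
  score <- rep(NA_real_, n)
  for (c_i in seq_len(n)) {
    w <- h[max(1L, c_i - half):min(n, c_i + half)]
    score[c_i] <- mean(w, na.rm = TRUE)
  }
  hit <- !is.na(score) & score >= threshold
  if (!any(hit)) return(empty)
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- cbind(start = starts[r$values], end = ends[r$values])
  # merge runs separated by < merge_gap residues
  merged <- seg[1, , drop = FALSE]
  if (nrow(seg) > 1) {
    for (k in 2:nrow(seg)) {
      gap <- seg[k, "start"] - merged[nrow(merged), "end"] - 1L
      if (gap < merge_gap) {
        merged[nrow(merged), "end"] <- seg[k, "end"]
      } else {
        merged <- rbind(merged, seg[k, , drop = FALSE])
      }
    }
  }
  keep <- (merged[, "end"] - merged[, "start"] + 1L) >= min_len
  merged <- merged[keep, , drop = FALSE]
  if (nrow(merged) == 0L) return(empty)
  mh <- vapply(seq_len(nrow(merged)), function(k) {
    s <- score[merged[k, "start"]:merged[k, "end"]]
    mean(s[!is.na(s) & s >= threshold])
  }, numeric(1))
  data.frame(start = as.integer(merged[, "start"]),
             end = as.integer(merged[, "end"]), mean_hydropathy = mh)
}
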