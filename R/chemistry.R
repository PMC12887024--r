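#' Titration records for AOAC reference chemistry
#'
#' Constructs a validated table of iodometric/Wijs titration quantities:
#' sample titration volume `S` (mL), blank volume `B` (mL), titrant
#' normality or molarity `N_or_M` (eq/L or mol/L sodium thiosulfate) and
#' sample mass `W` (g).  All arguments recycle to a common length.
#'
#' @param S,B Titration volumes in mL (>= 0).
#' @param N_or_M Thiosulfate normality (PV) or molarity (IV), > 0.
#' @param W Sample mass in g, > 0.
#' @param sample_id Optional identifiers.
#' @return A data frame of class `titration_record`.
#' @export
titration_record <- function(S, B, N_or_M, W, sample_id = NULL) {
  rec <- data.frame(S = S, B = B, N_or_M = N_or_M, W = W)
  if (!is.null(sample_id)) rec <- cbind(sample_id = sample_id, rec)
  if (any(!is.finite(rec$S)) || any(rec$S < 0) || any(rec$B < 0)) {
    stop_invalid("titration volumes must be finite and >= 0")
  }
  if (any(rec$N_or_M <= 0)) stop_invalid("titrant concentration must be > 0")
  if (any(rec$W <= 0)) stop_invalid("sample mass W must be > 0")
  class(rec) <- c("titration_record", class(rec))
  rec
}

#' Peroxide value from an iodometric titration (AOAC 965.33)
#'
#' \deqn{PV = \frac{(S - B) \times N \times 1000}{W}}
#' in meq O2 per kg of oil, where `S` and `B` are the sample and blank
#' thiosulfate volumes (mL), `N` the thiosulfate normality and `W` the
#' sample mass (g).
#'
#' @param rec A [titration_record()] (vectorized over rows).
#' @return Numeric vector of peroxide values, meq O2/kg.
#' @export
peroxide_value <- function(rec) {
  if (any(rec$S < rec$B)) {
    stop_invalid("S < B would give a negative peroxide value; impossible titration")
  }
  (rec$S - rec$B) * rec$N_or_M * 1000 / rec$W
}

#' Iodine value from a Wijs titration (AOAC 993.20)
#'
#' \deqn{IV = \frac{(B - S) \times M \times 12.69}{W}}
#' in g I2 per 100 g of oil.  Here the blank consumes more thiosulfate than
#' the sample, so `B >= S`; 12.69 converts mol thiosulfate to g iodine per
#' 100 g and is treated as exact.
#'
#' @inheritParams peroxide_value
#' @return Numeric vector of iodine values, g I2/100 g.
#' @export
iodine_value <- function(rec) {
  if (any(rec$B < rec$S)) {
    stop_invalid("B < S would give a negative iodine value; impossible titration")
  }
  (rec$B - rec$S) * rec$N_or_M * 12.69 / rec$W
}

#' Invert the PV formula: sample volume producing a given peroxide value
#'
#' @param pv Target peroxide value, meq O2/kg (>= 0).
#' @param N Thiosulfate normality, eq/L.
#' @param W Sample mass, g.
#' @param B Blank volume, mL.
#' @return Sample titration volume S in mL; satisfies
#'   `peroxide_value(titration_record(S, B, N, W)) == pv` to 1e-10 relative.
#' @export
titration_from_pv <- function(pv, N, W, B = 0.2) {
  if (any(pv < 0)) stop_invalid("pv must be >= 0")
  if (any(N <= 0) || any(W <= 0)) stop_invalid("N and W must be > 0")
  B + pv * W / (N * 1000)
}

#' Invert the IV formula: sample volume producing a given iodine value
#'
#' @param iv Target iodine value, g I2/100 g (>= 0).
#' @param M Thiosulfate molarity, mol/L.
#' @param W Sample mass, g.
#' @param B Blank volume, mL; must be large enough that the implied sample
#'   volume is non-negative.
#' @return Sample titration volume S in mL.
#' @export
titration_from_iv <- function(iv, M, W, B = 25) {
  if (any(iv < 0)) stop_invalid("iv must be >= 0")
  if (any(M <= 0) || any(W <= 0)) stop_invalid("M and W must be > 0")
  S <- B - iv * W / (M * 12.69)
  if (any(S < 0)) {
    stop_invalid("blank volume B too small for the requested iodine value (S would be negative)")
  }
  S
}

#' Read a titration table from CSV
#'
#' Expects columns `sample_id` (optional), `S`, `B`, `N_or_M`, `W`.
#' @param path File path.
#' @return A [titration_record()].
#' @export
read_titration_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  titration_record(d$S, d$B, d$N_or_M, d$W, sample_id = d$sample_id)
}

#' Write a titration table to CSV
#' @param rec A [titration_record()].
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_titration_csv <- function(rec, path) {
  utils::write.csv(as.data.frame(rec), path, row.names = FALSE)
  invisible(path)
}
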