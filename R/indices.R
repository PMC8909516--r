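#' Names of the eight stress-sensitive spectral indices, in feature order
#'
#' This order is fixed: it is the channel order of the per-pixel feature
#' sequences fed to the GRU (input size 8).
#' @export
INDEX_NAMES <- c("REP", "CIred_edge", "MSR", "MCARI",
                 "NDVI", "RDVI", "NDRE1", "NDRE2")

# Scalar index formulas over band reflectances. REP estimates the red-edge
# inflection wavelength (nm) by four-band linear interpolation; the others are
# ratio or normalized-difference indices. RDVI and MSR are implemented in
# their four-band forms as used for this monitoring task: RDVI shares the
# NDVI structure with B7 in place of B8, and MSR is the B1-anchored red-edge
# ratio (B6 - B1)/(B5 - B1); see the methods vignette for the relation of
# these forms to the like-named broadband indices in the wider literature.
index_formulas <- list(
  REP        = function(b) 700 + 40 * (((b$B7 - b$B4) / 2 - b$B5) / (b$B6 - b$B5)),
  CIred_edge = function(b) b$B7 / b$B5 - 1,
  MSR        = function(b) (b$B6 - b$B1) / (b$B5 - b$B1),
  MCARI      = function(b) ((b$B5 - b$B4) - 0.2 * (b$B5 - b$B3)) * (b$B5 / b$B4),
  NDVI       = function(b) (b$B8 - b$B4) / (b$B8 + b$B4),
  RDVI       = function(b) (b$B7 - b$B4) / (b$B7 + b$B4),
  NDRE1      = function(b) (b$B6 - b$B5) / (b$B6 + b$B5),
  NDRE2      = function(b) (b$B7 - b$B5) / (b$B7 + b$B5)
)

# Denominators whose vanishing makes each index undefined.
index_denominators <- list(
  REP        = function(b) b$B6 - b$B5,
  CIred_edge = function(b) b$B5,
  MSR        = function(b) b$B5 - b$B1,
  MCARI      = function(b) b$B4,
  NDVI       = function(b) b$B8 + b$B4,
  RDVI       = function(b) b$B7 + b$B4,
  NDRE1      = function(b) b$B6 + b$B5,
  NDRE2      = function(b) b$B7 + b$B5
)

#' Compute the eight stress-sensitive spectral indices
#'
#' Evaluates, per pixel and date: red-edge position
#' `REP = 700 + 40 * (((B7 - B4)/2 - B5) / (B6 - B5))`, red-edge chlorophyll
#' index `CIred_edge = B7/B5 - 1`, `MSR = (B6 - B1)/(B5 - B1)`,
#' `MCARI = ((B5 - B4) - 0.2 (B5 - B3)) * (B5/B4)`, and the normalized
#' differences `NDVI = (B8 - B4)/(B8 + B4)`, `RDVI = (B7 - B4)/(B7 + B4)`,
#' `NDRE1 = (B6 - B5)/(B6 + B5)`, `NDRE2 = (B7 - B5)/(B7 + B5)`.
#'
#' Cells whose QA flag marks cloud, whose formula denominator is zero, or
#' whose result is non-finite are flagged invalid (value `NA`), never silently
#' zeroed.
#'
#' @param stack A `reflectance_stack` containing bands B1, B3, B4, B5, B6,
#'   B7, B8.
#' @return An object of class `index_stack`: `values` and logical `valid`
#'   arrays indexed by `(date, index, row, col)`, plus `dates` and `indices`.
#' @export
compute_indices <- function(stack) {
  need <- c("B1", "B3", "B4", "B5", "B6", "B7", "B8")
  missing_bands <- setdiff(need, stack$bands)
  if (length(missing_bands) > 0)
    stopf("compute_indices: stack is missing band(s) %s",
          paste(missing_bands, collapse = ", "))

  d <- dim(stack$values)
  nt <- d[1]; nr <- d[3]; nc <- d[4]
  ni <- length(INDEX_NAMES)
  values <- array(NA_real_, dim = c(nt, ni, nr, nc),
                  dimnames = list(NULL, INDEX_NAMES, NULL, NULL))
  valid <- array(FALSE, dim = c(nt, ni, nr, nc),
                 dimnames = list(NULL, INDEX_NAMES, NULL, NULL))

  band_pos <- match(need, stack$bands)
  names(band_pos) <- need
  for (t in seq_len(nt)) {
    b <- lapply(band_pos, function(j) stack$values[t, j, , ])
    qa_t <- stack$qa[t, , ]
    for (i in seq_len(ni)) {
      nm <- INDEX_NAMES[i]
      den <- index_denominators[[nm]](b)
      val <- index_formulas[[nm]](b)
      ok <- qa_t & den != 0 & is.finite(val)
      val[!ok] <- NA_real_
      values[t, i, , ] <- val
      valid[t, i, , ] <- ok
    }
  }
  structure(list(values = values, valid = valid,
                 dates = stack$dates, indices = INDEX_NAMES),
            class = "index_stack")
}

#' @export
print.index_stack <- function(x, ...) {
  d <- dim(x$values)
  cat("<index_stack> ", d[1], " dates x ", d[2], " indices x ",
      d[3], "x", d[4], " pixels; ", signif(mean(!x$valid), 3),
      " invalid\n", sep = "")
  cat("  indices: ", paste(x$indices, collapse = ", "), "\n", sep = "")
  invisible(x)
}
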