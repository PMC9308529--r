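# Shared fixtures, built in code.

defaultProps <- tissuePropertyTable()
defaultBlood <- bloodProperties()

# uniform single-tissue map with a 1-pixel background border
uniformMap <- function(n, tissue = "WM", spacing = 2) {
  legend <- tissueLegend()
  lab <- matrix(legend[[tissue]], n, n)
  lab[c(1, n), ] <- legend[["background"]]
  lab[, c(1, n)] <- legend[["background"]]
  TissueLabelMap(lab, spacing = spacing)
}

# exactly left-right mirror-symmetric phantom with a centered lesion:
# odd column count, ellipse center on the middle column, no jitter
symmetricLesionMap <- function(rows = 48, cols = 49, spacing = 2) {
  legend <- tissueLegend()
  ci <- (rows + 1) / 2; cj <- (cols + 1) / 2
  a <- rows / 2 - 2; b <- (cols - 1) / 2 - 2
  i <- matrix(seq_len(rows), rows, cols)
  j <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  r <- sqrt(((i - ci) / a)^2 + ((j - cj) / b)^2)
  lab <- matrix(legend[["background"]], rows, cols)
  lab[r <= 1] <- legend[["CSF"]]
  lab[r <= 0.92] <- legend[["GM"]]
  lab[r <= 0.80] <- legend[["WM"]]
  map <- TissueLabelMap(lab, spacing = spacing)
  embedLesion(map, lesionSpec(center = c(round(ci), cj)))
}
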