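# Shared fixtures and independent oracles for the test suite.

test_coords <- function(length_bp = 3800, acs_offset = 1700,
                        orientation = "forward") {
  template_coords("ARS1_tpl", length_bp, acs_offset, orientation)
}

# Brute-force per-base Gaussian KDE: the independent oracle for build_track().
# Deliberately a naive double loop over (position, midpoint).
brute_force_track <- function(midpoints, length_bp, sigma = 20, trunc_sd = 3) {
  values <- numeric(length_bp)
  for (x in seq_len(length_bp) - 1L) {
    for (m in midpoints) {
      if (abs(x - m) <= ceiling(trunc_sd * sigma)) {
        values[x + 1L] <- values[x + 1L] + dnorm(x, mean = m, sd = sigma)
      }
    }
  }
  values
}

# Normalized track with a single synthetic Gaussian bump (for peak tests).
bump_track <- function(coords, centre, height, sigma = 20) {
  pos <- seq_len(coords$length_bp) - 1L
  vals <- height * exp(-((pos - centre)^2) / (2 * sigma^2))
  new_dyad_track(vals, coords, n_midpoints = 1L, normalized = TRUE)
}

# Minimal two-line proper-pair SAM fixture written to a temp file.
write_sam_fixture <- function(path, template_id = "ARS1_tpl", length_bp = 3800,
                              pos = 101L, tlen = 150L) {
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", template_id, length_bp),
    sprintf(
      "frag1\t99\t%s\t%d\t42\t36M\t=\t%d\t%d\t%s\t%s",
      template_id, pos, pos + tlen - 36L, tlen,
      strrep("A", 36), strrep("I", 36)
    ),
    sprintf(
      "frag1\t147\t%s\t%d\t42\t36M\t=\t%d\t%d\t%s\t%s",
      template_id, pos + tlen - 36L, pos, -tlen,
      strrep("A", 36), strrep("I", 36)
    )
  )
  writeLines(lines, path)
  path
}
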