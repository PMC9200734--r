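# Shared fixture builders. Everything is generated in code; no binary data.

cyl_stack <- function(r = 2, L = 8, n = 30) {
  disc_stack(cbind(rep(r, n), rep(r, n)), L, L)
}

# Midpoint-sampled hemi-ellipsoid cavity stack (the default phantom cavity).
hemi_stack <- function(b = 2.5, cc = b, L = 8, n = 30) {
  z <- (seq_len(n) - 0.5) * L / n
  s <- sqrt(pmax(0, 1 - (z / L)^2))
  disc_stack(cbind(b * s, cc * s), L, L)
}

rect_contour <- function(half_width = 2, L = 8) {
  planar_contour(
    cbind(c(-half_width, -half_width, half_width, half_width), c(0, L, L, 0)),
    base_left = c(-half_width, 0), base_right = c(half_width, 0),
    apex = c(0, L)
  )
}

semi_ellipse_contour <- function(b = 2, L = 8, n_side = 120) {
  u <- seq(0, pi / 2, length.out = n_side + 1)
  left <- cbind(-b * cos(u), L * sin(u))
  right <- cbind(b * cos(rev(u[-length(u)])), L * sin(rev(u[-length(u)])))
  planar_contour(rbind(left, right), base_left = c(-b, 0),
                 base_right = c(b, 0), apex = c(0, L))
}

# Raw (untyped) record matching inst/extdata/example_record.json.
example_raw_record <- function() {
  list(
    id = "example01",
    units = list(length = "cm", area = "cm2"),
    linear = list(ivs = 1.0, lvid = 4.5, pwt = 1.0),
    sax = list(a1 = 16 * pi, a2 = 9 * pi, level = "chordae"),
    long_axis = list(a = 4.8, d = 3.2),
    disc_stack = list(a = rep(2, 30), b = rep(2, 30),
                      length_4ch = 8, length_2ch = 8),
    subject = list(age_years = 45, sex = "M", bsa_m2 = 2.0)
  )
}

random_valid_raw_record <- function() {
  lvid <- runif(1, 3, 6)
  wall <- runif(2, 0.5, 1.5)
  r2 <- runif(1, 4, 25)
  r1 <- r2 + runif(1, 0, 20)
  L <- runif(1, 6, 10)
  n <- sample(5:40, 1)
  frac <- runif(1, 0.2, 0.6)
  list(
    id = paste0("r", sample(1e6, 1)),
    units = list(length = "cm", area = "cm2"),
    linear = list(ivs = wall[1], lvid = lvid, pwt = wall[2]),
    sax = list(a1 = r1, a2 = r2, level = "chordae"),
    long_axis = list(a = L * (1 - frac), d = L * frac),
    disc_stack = list(a = runif(n, 0, 3), b = runif(n, 0, 3),
                      length_4ch = L, length_2ch = L * runif(1, 0.9, 1.1)),
    subject = list(age_years = runif(1, 20, 80),
                   sex = sample(c("M", "F"), 1), bsa_m2 = runif(1, 1.5, 2.3))
  )
}
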