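# Shared fixtures and independent oracles, all built in code.

water_coords <- function() {
  data.frame(element = c("O", "H", "H"),
             x = c(0, 0.7572, -0.7572),
             y = c(0, 0.5865, 0.5865),
             z = c(0, 0, 0), stringsAsFactors = FALSE)
}

write_tmp_xyz <- function(coords, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".xyz", .local_envir = env)
  write_xyz(coords, path)
  path
}

# two-row stick table: the principal H-crystal transition plus a UV band
two_row_stick_tsv <- function(env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = env)
  writeLines(c("state\twavelength_nm\tf",
               "1\t333.17\t0.6249",
               "2\t216.0\t0.30"), path)
  path
}

# a small asymmetric 3D point cloud (non-planar, non-degenerate)
toy_points <- function(n = 4) {
  m <- matrix(c(0, 0, 0,
                1.5, 0, 0,
                0.3, 1.2, 0,
                0.2, 0.4, 1.1,
                -0.8, 0.9, 0.5,
                1.1, -0.7, 0.9), ncol = 3, byrow = TRUE)
  m[seq_len(n), , drop = FALSE]
}

rotmat_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
}

euler_rotation <- function(a, b, c) {
  rx <- matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3,
               byrow = TRUE)
  ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3,
               byrow = TRUE)
  rz <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3,
               byrow = TRUE)
  rz %*% ry %*% rx
}

# Independent RMSD oracle: exhaustive Euler-angle grid followed by local
# refinement (Nelder-Mead on the angles); translation handled by centering.
brute_force_rmsd <- function(a, b, grid_deg = 20) {
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  obj <- function(ang) {
    r <- euler_rotation(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((b %*% t(r) - a)^2)))
  }
  grid <- seq(0, 2 * pi - 1e-9, by = grid_deg * pi / 180)
  grid_b <- seq(0, pi, by = grid_deg * pi / 180)
  best <- NULL; best_val <- Inf
  for (x in grid) for (y in grid_b) for (z in grid) {
    v <- obj(c(x, y, z))
    if (v < best_val) { best_val <- v; best <- c(x, y, z) }
  }
  opt <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# Independent Spearman oracle: textbook formula on average ranks
brute_force_spearman <- function(x, y) {
  r <- function(v) vapply(seq_along(v), function(i)
    sum(v < v[i]) + (sum(v == v[i]) + 1) / 2, numeric(1))
  rx <- r(x); ry <- r(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# noise-free generator settings (deterministic links)
noise_free_spec <- function(seed, ...) {
  generator_spec(seed = seed,
                 potency_link = list(intercept = 20.4, slope = -2.9,
                                     noise_sd = 0),
                 shift_link = list(blue_fraction = 0.4, base_nm = 1.0,
                                   slope_nm = 0.6, noise_sd = 0),
                 ...)
}

# a tiny two-conformer + crystal ensemble built directly in code
tiny_ensemble <- function(crystal_strain_kcal = 1.346,
                          ic50_nM = NULL, dipoles = c(5.8, 4.2, 5.6)) {
  tpl <- scaffold_template("H")
  base <- -933.79888
  mk <- function(label, se, mu, role, phenyl = 0)
    conformer_record(label, base + se / 627.509474, mu,
                     quinspec:::apply_torsions(tpl, phenyl_deg = phenyl),
                     role)
  compound_ensemble(
    "H",
    list(mk("conf1", 0, dipoles[1], "global_minimum"),
         mk("conf2", 1.0, dipoles[2], "local_minimum", phenyl = 40),
         mk("crystal", crystal_strain_kcal, dipoles[3],
            "crystal_reference", phenyl = 25)),
    ic50_nM = ic50_nM, anchors = tpl$anchors)
}
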