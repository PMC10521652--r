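# Shared fixtures, generated once per test run.

fixture_env <- new.env()

fixture <- function(name, build) {
  if (!exists(name, envir = fixture_env, inherits = FALSE))
    assign(name, build(), envir = fixture_env)
  get(name, envir = fixture_env, inherits = FALSE)
}

ovoid_model <- function() fixture("ovoid", function() preset("ovoid"))
circular_model <- function() fixture("circular", function() preset("circular"))
zero_shear_model <- function() fixture("zero_shear", function() preset("zero_shear_toy"))
porin_model <- function() fixture("porin", function() preset("porin_like"))

ovoid_strands <- function()
  fixture("ovoid_strands", function() assign_strands(ovoid_model()))
circular_strands <- function()
  fixture("circular_strands", function() assign_strands(circular_model()))

# Minimal hand-built model: a row of residues along x with given amino
# acids; side chains point up in z.
toy_model <- function(aas, spacing = 3.8) {
  n <- length(aas)
  x <- (seq_len(n) - 1) * spacing
  cb <- ifelse(aas == "G", NA_real_, 1.0)
  new_barrel_model(tibble::tibble(
    residue = seq_len(n), aa = aas, element = "strand",
    n_x = x - 1.2, n_y = 0, n_z = 0,
    ca_x = x, ca_y = 0, ca_z = 0,
    c_x = x + 1.0, c_y = 0, c_z = 0,
    o_x = x + 1.0, o_y = 1.23, o_z = 0,
    cb_x = ifelse(is.na(cb), NA_real_, x),
    cb_y = ifelse(is.na(cb), NA_real_, 0),
    cb_z = cb), validate = FALSE)
}

# Place a side-chain atom cloud for residue i of a toy model.
with_sc <- function(model, residue, atoms, xyz) {
  i <- which(model$residue == residue)
  model$sc[[i]] <- tibble::tibble(atom = atoms, x = xyz[, 1], y = xyz[, 2],
                                  z = xyz[, 3])
  model
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2+z^2), 2*(x*y - w*z), 2*(x*z + w*y),
           2*(x*y + w*z), 1 - 2*(x^2+z^2), 2*(y*z - w*x),
           2*(x*z - w*y), 2*(y*z + w*x), 1 - 2*(x^2+y^2)), 3, 3)
}

# Apply a rigid motion to every coordinate of a model.
transform_model <- function(model, R, t = c(0, 0, 0)) {
  for (a in c("n", "ca", "c", "o", "cb")) {
    cc <- paste0(a, c("_x", "_y", "_z"))
    xyz <- as.matrix(model[, cc])
    ok <- stats::complete.cases(xyz)
    xyz[ok, ] <- sweep(xyz[ok, , drop = FALSE] %*% t(R), 2, t, `+`)
    model[, cc] <- xyz
  }
  model$sc <- lapply(model$sc, function(s) {
    if (is.null(s) || nrow(s) == 0) return(s)
    m <- sweep(as.matrix(s[, c("x", "y", "z")]) %*% t(R), 2, t, `+`)
    s$x <- m[, 1]; s$y <- m[, 2]; s$z <- m[, 3]
    s
  })
  model
}
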