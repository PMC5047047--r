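# Shared fixtures, built in code. The heavier phantom/model objects are
# memoised so several test files can reuse one resolution run.

fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, force(expr), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

# small absorbance image with known content
tiny_image <- function(nr = 4, nc = 5, axis = wn_axis(1000, 1100, 2)) {
  set.seed(99)
  cube <- array(stats::runif(nr * nc * length(axis)), c(nr, nc, length(axis)))
  hyper_image(cube, axis)
}

# default phantom + preprocessing (the study conditions)
default_phantom <- function() memo("default_phantom", {
  ph <- generate_phantom(phantom_config())
  d2 <- second_derivative(ph$image)
  mask <- compute_mask(d2)
  list(ph = ph, d2 = d2, mask = mask)
})

# resolved 5-factor model on the default phantom
default_model <- function() memo("default_model", {
  fx <- default_phantom()
  resolve(fx$d2, fx$mask, k = 5, region = c(950, 1300))
})

default_assignment <- function() memo("default_assignment", {
  assign_factors(default_model(), default_library())
})

# true concentration column (masked pixels, row-major) for one component
true_concentration <- function(ph, mask, component) {
  sel <- as.vector(t(unclass(mask)))
  grid <- ph$ground_truth$true_concentrations[, , component]
  as.vector(t(grid))[sel]
}

# negated 2nd-derivative library profiles on a region, unit norm
true_profiles <- function(lib, lo, hi, components) {
  refs <- library_second_derivative(lib, negate = TRUE)
  idx <- which(lib$axis >= lo & lib$axis <= hi)
  S <- vapply(components, function(nm) refs[[nm]]$intensities[idx],
              numeric(length(idx)))
  apply(S, 2, function(v) v / sqrt(sum(v^2)))
}

# exact optimum of the square assignment problem by enumeration (oracle)
best_permutation <- function(M) {
  k <- nrow(M)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(q) c(v[i], q))))
  }
  best <- -Inf; bp <- NULL
  for (p in perms(seq_len(k))) {
    s <- sum(M[cbind(seq_len(k), p)])
    if (s > best) { best <- s; bp <- p }
  }
  bp
}

# matched recovery scores of a model against phantom ground truth
recovery_scores <- function(model, ph, mask, lib) {
  comps <- ph$ground_truth$components
  S_true <- true_profiles(lib, model$region[1], model$region[2], comps)
  C_true <- vapply(comps, function(nm) true_concentration(ph, mask, nm),
                   numeric(nrow(model$C)))
  p <- best_permutation(abs(stats::cor(model$S, S_true)))
  list(components = comps[p],
       spectral = abs(stats::cor(model$S, S_true))[cbind(seq_along(p), p)],
       concentration = abs(stats::cor(model$C, C_true))[cbind(seq_along(p), p)])
}
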