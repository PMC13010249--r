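# shared test fixtures: small grids, random slab stacks, brute-force oracles

tiny_q <- function(n = 60) exp(seq(log(0.012), log(0.28), length.out = n))

# random physical slab stack (fronting silicon-like, backing solvent-like)
rand_stack <- function(n_interior = 3, rough_max = 3) {
  slab_stack(
    thickness = c(0, runif(n_interior, 5, 200), 0),
    sld = c(2.07, runif(n_interior, -0.5, 7), runif(1, -0.56, 6.36)),
    rough = c(0, runif(n_interior + 1, 0, rough_max))
  )
}

# independent atom-by-atom SLD summation (oracle for component_sld)
brute_force_sld <- function(comp, d2o_fraction, exchange_fraction = NULL) {
  b <- scattering_lengths()
  f <- if (is.null(exchange_fraction)) comp$exchange_fraction else exchange_fraction
  total <- 0
  for (el in names(comp$counts)) {
    n <- comp$counts[[el]]
    if (el == "H") {
      n_ex <- comp$exchangeable_h
      n_non <- n - n_ex
      # non-labile H: deuterated fraction
      total <- total + n_non * (1 - comp$deuteration) * b[["H"]]
      total <- total + n_non * comp$deuteration * b[["D"]]
      # labile H: solvent exchange
      x <- d2o_fraction * f
      total <- total + n_ex * ((1 - x) * b[["H"]] + x * b[["D"]])
    } else {
      total <- total + n * b[[el]]
    }
  }
  10 * total / comp$volume
}

# small membrane problem for optimizer tests (cheap forward model)
small_problem <- function(noise_rel = 0, seed = 1, n_q = 50,
                          contrasts = list(solvent_contrast(1),
                                           solvent_contrast(0)),
                          free = list(tail_thickness = c(20, 40)),
                          background = 1e-7) {
  s <- membrane_structure(bcl2_fraction = 0.2,
                          surface_layers = data.frame(
                            thickness = 40, coverage = 0.2,
                            component = "h_bax"))
  ds <- simulate_contrast_set(s, contrasts = contrasts, q = tiny_q(n_q),
                              noise_rel = noise_rel, background = background,
                              seed = seed)
  list(structure = s,
       problem = fit_problem(s, ds, free, free_backgrounds = FALSE))
}

fast_control <- list(maxiter = 40, de_tol = 1e-6, polish_maxit = 400)
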