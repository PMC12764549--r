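# Small fixtures shared across test files. Everything is generated in code.

# plain random composition matrix with reproducible values
make_composition <- function(m = 6, d = 10, seed = 1) {
  set.seed(seed)
  vals <- matrix(runif(m * d, 0, 5), m, d,
                 dimnames = list(paste0("med", seq_len(m)),
                                 paste0("cmp", seq_len(d))))
  composition_matrix(vals)
}

# duplicated-feature fixture: one predictive signal copied into `copies`
# identical columns, plus independent nuisance columns; a ridge model with
# a small fixed penalty spreads its weight evenly across the copies.
make_duplicate_fixture <- function(n = 200, copies = 5, noise_cols = 5,
                                   seed = 42) {
  set.seed(seed)
  base <- runif(n, 0, 4)
  X <- matrix(rep(base, copies), n, copies)
  X <- cbind(X, matrix(runif(n * noise_cols, 0, 4), n, noise_cols))
  colnames(X) <- c(paste0("dup", seq_len(copies)),
                   paste0("noise", seq_len(noise_cols)))
  y <- 2 * base + rnorm(n, 0, 0.3)
  ds <- culture_dataset(paste0("cond", seq_len(n)), rep(1, n), X, y)
  split <- grouped_split(ds, 0.6, seed = seed + 1)
  model <- tune_and_fit("ridge", split$train, folds = 3, seed = seed + 2,
                        grid = list(list(lambda = 0.05)))
  list(model = model, train = split$train, test = split$test)
}

# full design -> response -> linear suite -> adjusted-PFI consensus run,
# the end-to-end screening pipeline on generated data
run_screening_pipeline <- function(seed, spec = synth_spec(seed = seed),
                                   n_conditions = 120, design_iters = 3000,
                                   J = 10) {
  A <- synth_composition(spec)
  des <- design_blending(A, n_conditions, seed = seed + 1000,
                         iters = design_iters)
  Xc <- condition_compositions(des, A)
  resp <- synth_response(Xc, spec, seed = seed + 2000)
  suite <- run_model_suite(resp$dataset, models = linear_model_names(),
                           seed = seed + 3000)
  shrink <- shrunk_correlations(suite$split$train$X)
  tables <- lapply(suite$models, function(mdl)
    adjusted_pfi(mdl, suite$split$test$X, suite$split$test$y, shrink,
                 J = J, seed = seed + 4000))
  consensus <- consensus_components(tables, 0.25)
  list(composition = A, design = des, response = resp, suite = suite,
       tables = tables, consensus = consensus,
       recovered = length(intersect(consensus$consensus,
                                    resp$truth$planted)))
}

# memoized heavy simulation runs shared by several acceptance blocks
.sim_cache <- new.env(parent = emptyenv())

cached_default_sims <- function(seeds = 101:105) {
  key <- paste0("default_", paste(seeds, collapse = "_"))
  if (!exists(key, envir = .sim_cache)) {
    sims <- lapply(seeds, function(s)
      simulate_mother_media(simulation_config(seed = s)))
    assign(key, sims, envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

cached_wide_sims <- function(seeds = 201:205) {
  key <- paste0("wide_", paste(seeds, collapse = "_"))
  if (!exists(key, envir = .sim_cache)) {
    sims <- lapply(seeds, function(s)
      simulate_mother_media(simulation_config(n_media = 12,
                                              n_components = 100, seed = s)))
    assign(key, sims, envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

# all permutations of seq_len(n), for tiny exhaustive oracles
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- all_perms(n - 1L)
    for (p in rest) {
      q <- integer(n); q[1] <- i
      q[-1] <- setdiff(seq_len(n), i)[p]
      out[[length(out) + 1L]] <- q
    }
  }
  out
}
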