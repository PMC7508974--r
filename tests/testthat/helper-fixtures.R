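# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- fn()
  .fixtures[[key]]
}

fx_layout <- function() memo("layout", function() vf_layout("right"))

fx_truth <- function() memo("truth", function() normative_truth(fx_layout()))

# fitted normative model from a simulated non-glaucoma cohort
fx_norm <- function() {
  memo("norm", function() {
    set.seed(2024)
    cohort <- lapply(1:300, function(i) {
      sample_normal_field(runif(1, 25, 80), fx_truth(),
                          id = sprintf("norm%03d", i))
    })
    fit_normative(cohort)
  })
}

# the trained six-class glyph classifier, shared by the recognition tests
fx_glyph <- function() {
  memo("glyph", function() {
    train_glyph_model(n_plates = 60, params = capture_params(),
                      epochs = 12, seed = 424)
  })
}

# a small separable cohort and PDP classifier for behaviour tests
fx_small_cohort <- function() {
  memo("small_cohort", function() {
    cfg <- sim_config(n_records = 500,
                      class_mix = c(normal = 0.5, arcuate_sup = 0.25,
                                    advanced = 0.25),
                      severity_range = c(10, 18), seed = 31)
    simulate_cohort(cfg, fx_truth(), fx_layout())
  })
}

fx_small_model <- function() {
  memo("small_model", function() {
    train_vf_model(build_vf_model("PDP", seed = 5),
                   fx_small_cohort()$records, norm = fx_norm(),
                   epochs = 10, patience = 4, seed = 5)
  })
}

# random sparse probability-category maps for defect-rule tests
random_pd_cat <- function(n = 52) {
  sample(0:4, n, replace = TRUE, prob = c(0.70, 0.12, 0.08, 0.05, 0.05))
}

# independent union-find clustering oracle (merges over all pairs)
uf_clusters <- function(eligible, adj) {
  parent <- seq_along(eligible)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  idx <- which(eligible)
  for (a in idx) for (b in idx) {
    if (a < b && adj[a, b]) {
      ra <- find(a)
      rb <- find(b)
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(idx, find, integer(1))
  unname(split(idx, roots))
}

# pair-counting AUC oracle (ties count one half)
pair_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}
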