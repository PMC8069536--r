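# Shared fixtures. Heavy objects (full-genome workspaces, the seed-42
# design evaluations, the segmental panels) are built once per test run
# and memoized here.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache, inherits = FALSE)
}

# A small two-chromosome grid for plumbing tests.
tiny_bins <- function() {
  g <- genome_build(bin_size_bp = 1000000L, scale = 0.1)
  make_bins(g, seed = 3L)
}

fixture_workspace <- function(name) {
  cached(paste0("ws_", name), {
    profile_workspace(platform_profile(name), master_seed = 42L)
  })
}

fixture_design_eval <- function(name) {
  cached(paste0("eval_", name), {
    ws <- fixture_workspace(name)
    design <- simulate_design(ws$profile, ws$bins, cell_count = 10L,
                              seed = derive_seed(42L, "design", ws$profile$name))
    list(design = design, eval = evaluate_design(design, ws))
  })
}

fixture_panel <- function(name) {
  cached(paste0("panel_", name), {
    ws <- fixture_workspace(name)
    run_segmental_panel(ws, seed = derive_seed(42L, "panel", ws$profile$name))
  })
}

fixture_registry <- function() {
  cached("registry", karyotype_registry())
}

# Euploid profile-A sample + normalized profile on the workspace grid.
fixture_euploid_profile <- function(seed = 101L) {
  ws <- fixture_workspace("A")
  m <- cell_mixture(list(fixture_registry()[["46,XY"]]), 1, 10L)
  b <- simulate_bincounts(m, ws$profile, ws$bins, seed)
  gc_normalize(b, insilico_reference(ws$bins, ws$profile), ws$bins)
}

# Brute-force Clopper-Pearson bounds by bisection on the binomial CDF:
# the independent oracle the closed-form implementation is checked
# against.
cp_bisect <- function(x, n, alpha = 0.05, tol = 1e-12) {
  bisect <- function(f, lo, hi) {
    flo <- f(lo)
    for (i in 1:100) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      if (sign(fm) == sign(flo)) {
        lo <- mid
        flo <- fm
      } else {
        hi <- mid
      }
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }
  # Lower bound: p with P(X >= x | p) = alpha/2.
  lower <- if (x == 0) 0 else {
    bisect(function(p) stats::pbinom(x - 1, n, p) - (1 - alpha / 2), 0, 1)
  }
  # Upper bound: p with P(X <= x | p) = alpha/2.
  upper <- if (x == n) 1 else {
    bisect(function(p) stats::pbinom(x, n, p) - alpha / 2, 0, 1)
  }
  c(lower = lower, upper = upper)
}
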