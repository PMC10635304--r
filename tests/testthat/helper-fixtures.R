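# Shared fixtures, all generated in code.

default_acq <- cest_acquisition()

# a brain-like tissue state used across tests
test_tissue <- function(r_amines = 1, r_MT = 1)
  cest_tissue(R1w = 0.55, R2w = 25, R1M = 1, fm = 0.09,
              r_amines = r_amines, r_MT = r_MT)

test_amide <- function(fs = 1e-3, ksw = 50, R2s = 30)
  cest_pool("amide", fs, ksw, 3.5, R2s = R2s)

# two-pool (water + amide) set for oracle comparisons
two_pool_set <- function(fs = 1e-3, ksw = 50, R2s = 30,
                         R1w = 0.5, R2w = 25)
  pool_set(cest_pool("water", 1, 0, 0, R1s = R1w, R2s = R2w),
           cest_pool("amide", fs, ksw, 3.5, R2s = R2s))

# six-Lorentzian ground truth used by the generate-and-refit tests
test_lorentzian_truth <- function()
  data.frame(pool = c("amide", "amine", "water", "noe16", "noe35", "mt"),
             A = c(0.03, 0.08, 0.75, 0.04, 0.12, 0.10),
             W = c(1.8, 4.5, 1.6, 2.5, 4.2, 45),
             delta = c(3.52, 2.1, 0.02, -1.62, -3.45, -2.5))

# spectrum synthesized from the six-line model 1 - sum L_i
synth_from_lorentzians <- function(truth = test_lorentzian_truth(),
                                   offsets = default_acq$offsets) {
  s <- rep(1, length(offsets))
  for (i in seq_len(nrow(truth)))
    s <- s - lorentzian_line(truth$A[i], truth$W[i], truth$delta[i], offsets)
  zspectrum(offsets, s)
}

# small measured-component bundle fitted off one simulated spectrum;
# cached because several files need it
measured_from_simulation <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      rec <- sample_tissue_mimicking(n = 1, seed = 404)[[1]]
      fit <- fit_multipool(rec$z)
      cache <<- list(
        mc = extract_measured_components(fit, rec$tissue$R1obs,
                                         rec$tissue$fm),
        rec = rec, fit = fit)
    }
    cache
  }
})
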