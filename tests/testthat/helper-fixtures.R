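# Shared fixture builders: everything is generated in code at test time.

# small default geometry used across tests (3.2 deg field, 20 px/deg)
tiny_geom <- list(extent_deg = 3.2, n_pixels = 64)

make_tiny_grating <- function(theta = 0, f = 5, phase = 0, ...) {
  make_grating(grating_params(theta, f, phase, ...),
               extent_deg = tiny_geom$extent_deg,
               n_pixels = tiny_geom$n_pixels)
}

# two-filter truth set used by several fitting tests
two_filter_truth <- function(K = -0.3) {
  filter_set(
    list(grating_params(0, 5, 0, K = K, T_sat = 1, A = 0.8),
         grating_params(30, 5, 120, K = K, T_sat = 1, A = 0.4)),
    weights = c(0.8, 0.4))
}

# noiseless CSF tables from known parameters
csf_table_from <- function(params, sfs = c(0.5, 1, 1.25, 2, 2.5, 4, 5, 8)) {
  data.frame(sf_cpd = sfs, sensitivity = csf_eval(params, sfs))
}

oracle_script <- function() {
  system.file("oracle", "nlpd_reference.py", package = "amblyosim")
}

nlpd_via_python <- function(a, b, n_scales, const = 0.17, pool = 3,
                            include_lowpass = TRUE) {
  fa <- tempfile(fileext = ".csv")
  fb <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fa, fb)), add = TRUE)
  write.table(a, fa, sep = ",", row.names = FALSE, col.names = FALSE)
  write.table(b, fb, sep = ",", row.names = FALSE, col.names = FALSE)
  out <- system2("python", c(oracle_script(), fa, fb, n_scales, const, pool,
                             if (include_lowpass) "1" else "0"),
                 stdout = TRUE)
  as.numeric(out[length(out)])
}
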