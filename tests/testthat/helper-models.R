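# shared fixtures, built in code

passive_single <- function(g_leak = 0.1, c_m = 1) {
  cell_params(list(compartment_params("S", c_m = c_m, g_leak = g_leak)))
}

passive_three <- function() zero_channels(make_three_compartment_trn())

# a coupled pair of passive single-compartment cells
passive_pair <- function(g_12, g_21 = g_12, g_leak = 0.1) {
  coupled_pair(c("S", "S"), g_12 = g_12, g_21 = g_21,
               cell1 = passive_single(g_leak), cell2 = passive_single(g_leak))
}

# direct O(n*K) cross-correlation used as oracle for the fft-based one
direct_xcorr <- function(f1, f2, K) {
  vapply(-K:K, function(k) {
    t <- seq_along(f1); tk <- t + k
    ok <- tk >= 1 & tk <= length(f2)
    sum(f1[t[ok]] * f2[tk[ok]])
  }, numeric(1))
}
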