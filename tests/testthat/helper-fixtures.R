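# Shared fixtures built in code.

# A hand-built track table with one track violating each filter rule and
# one clean survivor.  Field: 20 x 20 um movie of 100 frames.
toy_track_table <- function() {
  mk <- function(id, frames, x, y) {
    data.frame(track_id = id, frame = frames, t = frames * 0.05,
               x = x, y = y, intensity = 5500)
  }
  rbind(
    mk(1, 1:5,  seq(10, 10.4, by = 0.1), rep(10, 5)),      # starts in frame 1
    mk(2, 96:100, seq(10, 10.4, by = 0.1), rep(10, 5)),    # present in last frame
    mk(3, 10:11, c(10, 10.1), c(10, 10.1)),                # <= 2 frames
    mk(4, 20:26, rep(10, 7), rep(10, 7)),                  # immobile
    mk(5, 30:36, seq(0.2, 0.8, by = 0.1), rep(10, 7)),     # near edge
    mk(6, 50:56, seq(10, 10.6, by = 0.1), seq(10, 10.6, by = 0.1))  # clean
  )
}

# exponential mixture survival evaluated at t
mix_survival <- function(t, taus, fractions) {
  rowSums(vapply(seq_along(taus),
                 function(i) fractions[i] * exp(-t / taus[i]),
                 numeric(length(t))))
}

# deterministic dwell sample from inverse-CDF quantiles (noise-free)
quantile_dwells <- function(n, tau) -tau * log(1 - stats::ppoints(n))

# deterministic Rayleigh step sample from inverse-CDF quantiles
quantile_steps <- function(n, D, tau) sqrt(-4 * D * tau * log(1 - stats::ppoints(n)))
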