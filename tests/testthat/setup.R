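# Shared simulation fixtures, computed once per test run (the reference
# trajectories are reused by several files).
shared <- new.env(parent = emptyenv())

shared_traj <- function(key, fun) {
  if (is.null(shared[[key]])) shared[[key]] <- fun()
  shared[[key]]
}

tr_split <- function() shared_traj("split", function() {
  simulate_full(ps_timescale_split())
})
tr_bimS <- function() shared_traj("bimS", function() {
  simulate_full(ps_bimodal_S())
})
tr_bimI <- function() shared_traj("bimI", function() {
  simulate_full(ps_bimodal_I())
})
tr_bal <- function() shared_traj("bal", function() {
  simulate_full(ps_balanced())
})
tr_part <- function() shared_traj("part", function() {
  simulate_partial(ps_partial())
})
ev_of <- function(key, trfun) shared_traj(paste0("ev_", key), function() {
  detect_steady_states(trfun())
})
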