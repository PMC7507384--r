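# Shared fixtures. Networks are built in code; expensive solves are cached
# per session so independent test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# two nodes, one segment (inlet -- outlet)
two_node_net <- function(D = 8.3, L = 20.9) {
  glom_network(
    nodes = data.frame(id = 1:2, kind = c("afferent_inlet", "efferent_outlet")),
    segments = data.frame(id = 1L, i = 1L, j = 2L, L_um = L, D_um = D))
}

# inlet - A - B - outlet chain
chain_net <- function(n_interior = 2, D = 8.3, L = 20.9) {
  n <- n_interior + 2
  glom_network(
    nodes = data.frame(id = seq_len(n),
                       kind = c("afferent_inlet", rep("interior", n_interior),
                                "efferent_outlet")),
    segments = data.frame(id = seq_len(n - 1), i = seq_len(n - 1),
                          j = seq_len(n - 1) + 1, L_um = L, D_um = D))
}

# inlet splits into two parallel branches that rejoin before the outlet
diamond_net <- function(D = c(10, 8, 8, 10), L = 20) {
  glom_network(
    nodes = data.frame(id = 1:4, kind = c("afferent_inlet", "interior",
                                          "interior", "efferent_outlet")),
    segments = data.frame(id = 1:4, i = c(1, 2, 2, 3), j = c(2, 3, 3, 4),
                          L_um = L, D_um = D))
}

# reduced Shea-like preset: same construction, ~1/3 of the segments; used
# where a full anatomy is unnecessary (parameter recovery, directional suite)
small_params <- function() {
  generator_params(n_segments = 110, n_nodes = 69, lobules = 3,
                   total_area = 1.76e5 * 110 / 320)
}

default_net <- function() cached("default_net",
                                 generate_shea_like_network(shea_params(), seed = 1))

small_net <- function(seed = 1) cached(paste0("small_net", seed),
                                       generate_shea_like_network(small_params(), seed = seed))

base_bc <- function() boundary_conditions()

# base-case calibration on the default preset (the expensive shared fixture)
base_case_result <- function() cached("base_case_result",
                                      run_scenario(scenario_preset("base"), default_net()))

# a converged mid-range operating point on the default preset
default_state <- function() cached("default_state",
                                   fixed_point_solve(default_net(),
                                                     boundary_conditions(R_AA = 2.5e10, R_EA = 1.7e10),
                                                     k = 2e-5))
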