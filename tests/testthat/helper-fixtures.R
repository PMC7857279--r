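# Fixtures are built in code: a small hand-written two-focal dataset with
# easily checkable sums, and thin wrappers around the simulator.

toy_counts <- function() {
  groups <- expand.grid(group_label = c("B", "C", "D"),
                        replicate_id = c("W1", "W2"),
                        stringsAsFactors = FALSE)[, 2:1]
  groups$batch <- ifelse(groups$replicate_id == "W1", 1L, 2L)
  groups$total_matings <- c(10L, 8L, 12L, 20L, 20L, 20L)
  groups$focal_matings <- c(4L, 2L, 6L, 20L, 20L, 20L)
  recipients <- expand.grid(recipient_index = 1:4,
                            group_label = c("B", "C", "D"),
                            replicate_id = c("W1", "W2"),
                            stringsAsFactors = FALSE)[, 3:1]
  recipients$total_sperm <- rep(c(5L, 10L), each = 12)
  recipients$focal_sperm <- rep(c(2L, 10L), each = 12)
  recipients$egg_in_antrum <- FALSE
  recipients$total_offspring <- rep(c(3L, 6L), each = 12)
  recipients$focal_offspring <- rep(c(1L, 6L), each = 12)
  penetrance <- data.frame(replicate_id = c("W1", "W2"),
                           offspring_screened = c(40L, 50L),
                           gfp_positive = c(40L, 50L),
                           stringsAsFactors = FALSE)
  list(groups = groups, recipients = recipients, penetrance = penetrance)
}

toy_data <- function() {
  tc <- toy_counts()
  repsel_data(tc$groups, tc$recipients, tc$penetrance)
}

small_sim <- function(seed = 1L, n_focals = 40L, ...) {
  simulate_dataset(simulation_config(n_focals = n_focals, seed = seed, ...))
}

# aggregates table built directly (bypasses the data layer) for
# variance-module unit tests
manual_aggregates <- function(m_t, m_f, s_t, s_f, o_t, o_f,
                              batch = 1L) {
  data.frame(replicate_id = sprintf("R%02d", seq_along(m_t)),
             batch = batch, m_t = m_t, m_f = m_f, s_t = s_t, s_f = s_f,
             o_t = o_t, o_f = o_f, stringsAsFactors = FALSE)
}
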