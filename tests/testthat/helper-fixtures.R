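# Shared fixtures and a random-dataset generator for property tests.

flight_obs <- function() {
  read_flight_table(marsbmd_extdata("flight_table1.csv"))
}

table3_grid <- function() {
  utils::read.csv(marsbmd_extdata("table3_tscores.csv"),
                  stringsAsFactors = FALSE)
}

# the published fitted model (rounded rate as printed)
paper_model <- function() decay_model(6.371e-4)

# small random flight table scattered around a known curve
random_obs <- function(true_lambda = 6.371e-4, n_rows = sample(3:8, 1),
                       sd = 3) {
  t <- sort(stats::runif(n_rows, 30, 2500))
  m <- decay_model(true_lambda)
  y <- pmax(predict_loss(m, t) + stats::rnorm(n_rows, 0, sd), 0.1)
  data.frame(duration_days = t, loss_pct = y,
             n_astronauts = sample(1:50, n_rows, replace = TRUE))
}
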