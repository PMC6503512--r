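# Shared fixtures: built in code, no stored data.

# Table ages 0..max_age with no mortality until the (closed) terminal age.
immortal_life_table <- function(max_age = 110L) {
  q <- rep(0, max_age + 1L)
  q[max_age + 1L] <- 1
  peanutCEA:::new_life_table(q)
}

# Inputs with every stochastic event switched off: no mortality, no
# food-allergy fatality, no reactions, no therapy anaphylaxis, no
# discontinuation. The model then reduces to a closed-form annuity.
degenerate_inputs <- function() {
  inp <- default_inputs()
  inp$life_table <- immortal_life_table()
  inp$p_accidental_reaction <- 0
  inp$p_ed_anaphylaxis <- 0
  inp$fa_fatality_5_19 <- 0
  inp$fa_fatality_20plus <- 0
  inp$epit$p_tx_anaphylaxis <- 0
  inp$epit$p_discontinue_y1 <- 0
  inp$poit$p_tx_anaphylaxis <- 0
  inp$poit$p_discontinue_y1 <- 0
  inp
}

# Inputs with events off but default mortality retained.
no_event_inputs <- function() {
  inp <- degenerate_inputs()
  inp$life_table <- default_inputs()$life_table
  inp
}

annuity_80_3pct <- (1 - 1.03^-80) / 0.03  # closed-form geometric series

# Random-but-plausible arm results for algebraic property tests.
random_arm_result <- function(arm = "x") {
  structure(list(arm = arm,
                 mean_cost = stats::runif(1, 5e4, 3e5),
                 mean_qaly = stats::runif(1, 20, 30)),
            class = "arm_result")
}
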