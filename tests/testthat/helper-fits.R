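# cached small fitted models shared by behavior/control/io tests
tiny_behavior <- local({
  val <- NULL
  function() {
    if (is.null(val))
      val <<- suppressMessages(
        behavior_learner(tiny_records(), tiny_cohort(), groups = 2,
                         budget = 1200, seed = 11))
    val
  }
})
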