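# The overfit smoke model (depth-5 U-Net, 32 synthetic windows, 200 epochs,
# seed 123456) is expensive to train, so it is fitted once per test run and
# shared by every test that needs it.
smoke_traces <- local({
  traces <- NULL
  function() {
    if (is.null(traces)) traces <<- generate_dataset(32, seed = 123456)
    traces
  }
})

smoke_model <- local({
  fit <- NULL
  function() {
    if (is.null(fit))
      # capacity experiment: the regularizer is off because the test
      # measures how well the network can fit, not how well it generalizes
      fit <<- egm_segmenter(smoke_traces(), arch = "unet", depth = 5,
                            epochs = 200, seed = 123456, dropout = 0)
    fit
  }
})

# the shared batch of clinical recordings with programmed decrements
clinical_batch <- local({
  recs <- NULL
  function() {
    if (is.null(recs)) {
      pools <- local_pools()
      decs <- rep(c(0, 5, 15, 20, 40), length.out = 100)
      recs <<- lapply(seq_len(100), function(i) {
        set.seed(202500 + i)
        generate_clinical_recording(
          protocol_config(decrement_ms = decs[i]), pools)
      })
    }
    recs
  }
})
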