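## rule-trained fixture models, trained once per session on first use

rule_instances <- function(n = 1500L, sd_noise = 0.5, seed = 42L) {
  withr::with_seed(seed, {
    protos <- vapply(seq_len(n), function(.) rand_seq(20), "")
    rule <- blunt_rule_default()
    y <- rule$effect17[substr(protos, 17, 17)] +
      rule$effect18[substr(protos, 18, 18)] + rnorm(n, sd = sd_noise)
    tibble::tibble(protospacer = protos, spacer = protos,
                   response = as.numeric(y))
  })
}

fixture_model <- local({
  cache <- new.env(parent = emptyenv())
  function(flavor = "full") {
    if (is.null(cache[[flavor]])) {
      cache[[flavor]] <- train_blunt_model(
        rule_instances(), flavor = flavor, seed = 7L,
        nrounds = 60L, nfolds = 2L)
    }
    cache[[flavor]]
  }
})
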