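# Shared fixtures, built in code at test time.

# 64-tuple space used by brute-force oracles
tiny_space <- function() {
  hp_space(cld = 2L, ks_min = 3L, ks_max = 5L, ks_odd = TRUE,
           kc_min = 16L, kc_max = 17L, dlnc_min = 256L, dlnc_max = 257L)
}

# full-scale study space
full_space <- function() hp_space()

# small low-noise dataset shared by CNN tests (memoised per session)
.test_ds_env <- new.env()
test_dataset <- function() {
  if (is.null(.test_ds_env$ds)) {
    ds <- generate_dataset(n_subjects = 4, pieces_per_type = 15,
                           fs = 20, duration = 10, noise = 0.05, seed = 501)
    .test_ds_env$ds <- split_dataset(ds, n_train_pool = 240,
                                     val_fraction = 0.25, seed = 502)
  }
  .test_ds_env$ds
}

# brute-force keep-best-n oracle for harmony-memory updates: the final
# memory must hold the n best values ever seen (seeding entries included)
keep_best_oracle <- function(initial_r, candidate_r, n) {
  all_r <- c(initial_r, candidate_r)
  sort(all_r, decreasing = TRUE)[seq_len(n)]
}

expect_valid_hp <- function(space, hp) {
  v <- validate_hp(space, hp)
  expect_true(v$valid, info = paste(v$errors, collapse = "; "))
}
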