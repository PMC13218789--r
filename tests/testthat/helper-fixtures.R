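# Shared builders for test inputs. Everything is generated in code; no
# fixture files are stored.

write_lines_tmp <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

# 2-variant toy records used across phasing tests; calls given as strings
# like "C/T".
make_records <- function(genos, ids = NULL) {
  ids <- ids %||% sprintf("S%d", seq_along(genos))
  lapply(seq_along(genos), function(i) {
    calls <- lapply(strsplit(genos[[i]], ",", fixed = TRUE)[[1L]], function(cell) {
      if (cell == "?") NA else sort(strsplit(cell, "/", fixed = TRUE)[[1L]], method = "radix")
    })
    genotype_record(ids[[i]], calls)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_freqs <- c("*1" = 0.5, "*4" = 0.2, "*10" = 0.2, "*41" = 0.1)

# Star-frequency vector -> named haplotype-key frequency vector.
star_freqs_to_hap_freqs <- function(star_freqs, table) {
  idx <- match(names(star_freqs), table$stars$star)
  keys <- table$hap_keys[idx]
  stats::setNames(as.numeric(star_freqs), keys)
}

hap_key_of <- function(h) paste(h, collapse = "\x1f")

# An indeterminate activity score with the given bounds.
new_as_for_test <- function(bounds) {
  structure(list(value = NA_real_, indeterminate = TRUE, bounds = bounds,
                 flags = character(0)), class = "activity_score")
}

unclass_attr <- function(x) {
  attributes(x) <- NULL
  x
}

# A hap_freq_set with fixed frequencies (for phase_cohort tests that need
# exact control over the weights).
fixed_freq_set <- function(freq_by_key, wildcards) {
  keys <- sort(names(freq_by_key), method = "radix")
  haplotypes <- do.call(rbind, strsplit(keys, "\x1f", fixed = TRUE))
  structure(list(haplotypes = haplotypes, hap_keys = keys,
                 freq = unname(freq_by_key[keys]),
                 loglik = NA_real_, loglik_trace = numeric(0),
                 n_iter = 0L, converged = TRUE,
                 restart_logliks = numeric(0), n_samples = NA_real_,
                 wildcards = wildcards),
            class = "hap_freq_set")
}
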