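# small configurations used across tests (kept tiny so the suite stays fast)

small_cfg <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_genotypes = 6, n_sites = 4, n_replicates = 5, n_loci = 120,
         n_causal = 10, missing_combination = NULL, n_early_mortality = 0,
         seed = seed),
    list(...))
  do.call(sim_config, args)
}

# hand-built survey table: one fragment per row spec, scores recycled over
# timepoints
make_survey <- function(fragments, scores, timepoints = 3) {
  do.call(rbind, lapply(seq_len(nrow(fragments)), function(i) {
    data.frame(fragment_id = fragments$fragment_id[i],
               genotype_id = fragments$genotype_id[i],
               site_id = fragments$site_id[i],
               timepoint = seq_len(timepoints),
               score = rep_len(scores[[i]], timepoints),
               early_mortality = FALSE,
               survived_december = fragments$survived[i],
               stringsAsFactors = FALSE)
  }))
}

# constant-temperature series helper
const_series <- function(site = "sA", temp = 29, days = 7,
                         start = "2015-05-01") {
  hours <- seq(as.POSIXct(paste(start, "00:00:00"), tz = "UTC"),
               by = "hour", length.out = days * 24)
  data.frame(site_id = site, timestamp = hours, temp_c = temp,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
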