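# Shared, lazily computed full-pipeline runs (the spiking circuit is the
# expensive stage; every scenario is reused by several tests).
.run_cache <- new.env(parent = emptyenv())

cached_config <- function() {
  if (is.null(.run_cache$config)) .run_cache$config <- default_config()
  .run_cache$config
}

cached_run <- function(scenario) {
  key <- paste0("run_", scenario)
  if (is.null(.run_cache[[key]]))
    .run_cache[[key]] <- run_saccade(scenario, cached_config(),
                                     keep_sim = TRUE)
  .run_cache[[key]]
}

all_scenarios <- c("4deg", "8deg", "12deg", "16deg", "20deg")

# Burst/pause event times of the main populations, measured against the
# nominal saccade anchors (latent-period end and planned termination).
choreography <- function(run) {
  sp <- run$sim$spikes
  t1 <- run$times$t1
  tE <- run$times$t_end
  inwin <- function(id, a = t1 - 45, b = tE + 25) {
    s <- sp[[id]]
    s[s >= a & s <= b]
  }
  burst_bounds <- function(id, isi_max = 4, min_run = 3) {
    s <- inwin(id)
    if (length(s) < min_run + 1) return(c(NA_real_, NA_real_))
    d <- diff(s)
    runs <- rle(d < isi_max)
    idx <- cumsum(runs$lengths)
    good <- which(runs$values & runs$lengths >= min_run)
    if (!length(good)) return(c(NA_real_, NA_real_))
    first <- idx[good[1]] - runs$lengths[good[1]] + 1
    last <- idx[good[length(good)]] + 1
    c(s[first], s[last])
  }
  spo <- sp$OPN
  base_isi <- median(diff(spo[spo < t1 - 40]))
  g <- which.max(diff(spo))
  anb <- burst_bounds("AN_i")
  list(t1 = t1, t_end = tE,
       LLBN_on = min(inwin("LLBN_i", 60)) - t1,
       LLBN_off = max(inwin("LLBN_i")) - tE,
       OPN_pause_on = spo[g] + base_isi - t1,
       OPN_resume = spo[g + 1] - tE,
       EBN_on = min(inwin("EBN_i")) - t1,
       EBN_off = max(inwin("EBN_i", b = tE)) - tE,
       IBN_on = min(inwin("IBN_i")) - t1,
       IBN_off = max(inwin("IBN_i", b = tE)) - tE,
       AN_on = anb[1] - t1, AN_off = anb[2] - tE)
}
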