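# shared fixture builders: everything is generated in code at test time

minute_times <- function(n, start = "2016-10-03 00:00:00") {
  as.POSIXct(start, tz = "") + 60 * (seq_len(n) - 1L)
}

# a small well-formed particle count series
tiny_counts <- function(small = c(100L, 200L, 300L), large = c(20L, 30L, 40L)) {
  particle_count_series(minute_times(length(small)), small, large,
                        device_id = "unit")
}

# pm series from raw values on the minute grid
tiny_pm <- function(values, start = "2016-10-03 00:00:00", source = "unit") {
  pm_series(minute_times(length(values), start), values, source_id = source)
}

# a clean eligible cotinine record
make_record <- function(id = "W1", prison = "P1",
                        pre = 0.4, post = 0.5,
                        pre_cens = FALSE, post_cens = FALSE,
                        elapsed_h = 8,
                        smoker = FALSE, product = FALSE,
                        cohabitant = FALSE, vehicle = FALSE,
                        valid_pre = TRUE, valid_post = TRUE) {
  t0 <- as.POSIXct("2016-11-14 07:30", tz = "")
  structure(data.frame(
    participant_id = id, prison_id = prison,
    pre_time = t0, post_time = t0 + elapsed_h * 3600,
    pre_value = if (pre_cens) NA_real_ else pre, pre_censored = pre_cens,
    post_value = if (post_cens) NA_real_ else post, post_censored = post_cens,
    smoker = smoker, nicotine_product_user = product,
    smoking_cohabitant = cohabitant, smoking_vehicle = vehicle,
    valid_pre = valid_pre, valid_post = valid_post,
    valid_times = elapsed_h > 0,
    stringsAsFactors = FALSE
  ), class = c("cotinine_records", "data.frame"))
}

bind_records <- function(...) {
  structure(do.call(rbind, lapply(list(...), as.data.frame)),
            class = c("cotinine_records", "data.frame"))
}
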