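# tiny in-code fixtures used across test files

small_table <- function() {
  impact_table(data.frame(
    category = c("climate_change", "eutrophication_freshwater"),
    scenario = c("BT-2017", "BT-2017"),
    unit = c("kg CO2 eq", "kg P eq"),
    con_value = c(100, 2.0),
    dfm_value = c(90, 1.8)))
}

two_phase_plan <- function(fp1 = 0.5, fp2 = 0.4) {
  phase_plan(data.frame(
    duration_days = c(10L, 20L),
    daily_intake = c(1.5, 2.5),
    feed1_id = c("d1", "d2"), feed1_price = fp1,
    feed2_id = c("d2", "d3"), feed2_price = fp2))
}

# independent brute-force reduction used as an oracle against package code
brute_reduction <- function(con, dfm) (con - dfm) / con * 100
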