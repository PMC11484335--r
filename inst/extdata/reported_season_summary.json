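{
  "description": "Published 2022/23 influenza-season summary figures from the English primary-care sentinel surveillance network: old vs new ARI phenotyping algorithm. Used as inputs to the printed-arithmetic validation checks.",
  "season": "2022/23 (ISO weeks 2022-W39 to 2023-W38)",
  "part1_codelists": {
    "old_size": 821,
    "new_size": 544,
    "in_both": 417,
    "only_old": 404,
    "only_new": 127,
    "new_codes_used": 304,
    "new_top_codes": 25,
    "new_top_share_percent": 90.5,
    "old_codes_used": 346,
    "old_top_codes": 16,
    "old_top_share_percent": 90.6
  },
  "part2_cases": {
    "old_total": 2386443,
    "new_total": 3194224,
    "newly_included": 860039,
    "newly_excluded": 52258,
    "excluded_chronic": 22862,
    "excluded_non_infective": 15695,
    "excluded_recurrent": 7515,
    "urti_old": 1647236,
    "urti_new": 1862191,
    "ili_old": 47815,
    "ili_new": 47812
  },
  "part3_rates": {
    "old_cases_reliable": 1965341,
    "new_cases_reliable": 2478473,
    "old_median_weekly_rate": 205.6,
    "new_median_weekly_rate": 258.9,
    "urti_old_rate": 140.7,
    "urti_new_rate": 159.0,
    "ili_old_rate": 3.1,
    "ili_new_rate": 3.1
  }
}
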