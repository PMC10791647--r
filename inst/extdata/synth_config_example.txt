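# Example generator configuration (key = value; vectors comma-separated).
# Any key omitted here keeps the default of synth_config().
n_stock = 10000
year_range = 2010, 2014
sex_ratio_male = 0.49
birth_month_weights = 1.02, 0.96, 1.00, 1.00, 1.02, 1.00, 1.04, 1.04, 1.06, 1.02, 0.97, 0.97
weekend_birth_factor = 0.85
gompertz_a = 0.0001
gompertz_b = 0.09
season_death_weights = 1.30, 0.95, 0.85, 0.90
migration_rate_in = 0.02
migration_rate_out = 0.015
september_peak_factor = 1.5
jan1_heaping_rate = 0.05
fertility_rate = 0.009
seed = 2021
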