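measure	assessment	description
ADS_con	ADS	Loss of behavior control
ADS_obs	ADS	Obsessive drinking style
ADS_per	ADS	Psychoperceptual withdrawal
ADS_phy	ADS	Psychophysical withdrawal
ADS_tot	ADS	Total ADS
AUDIT_1	AUDIT	Frequency of drinking
AUDIT_2	AUDIT	Typical quantity per drinking day
AUDIT_3	AUDIT	Frequency of six or more drinks
AUDIT_tot	AUDIT	Total AUDIT score
ICS_total	ICS	Total ICS
ICS_ac	ICS	Attempted control
ICS_fc	ICS	Failed control
ICS_pc	ICS	Perceived control
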