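event_id,timestamp,behavior,actors,target
E01,00:00:10,PET,KS01;RR01,
E01,00:00:20,RUB,KS01;RR02,
E01,00:00:30,PET,KS01;RR03,
E01,00:00:40,RUB,KS02;RR01,
E01,00:00:50,PET,KS02;RR02,
E01,00:01:00,RUB,KS01;KS02,
E01,00:01:10,PET,KS01;KS03,
E01,00:01:20,RUB,KS02;KS03,
E01,00:01:30,PET,RR01;RR02,
E01,00:01:40,RUB,RR01;RR03,
E01,00:01:50,D0,KS02;RR03,
E01,00:02:00,SYNCH,KS01;RR01,
E01,00:02:10,SYNCH,KS01;KS02,
E01,00:02:20,SYNCH,RR01;RR02,
E02,00:00:10,D0,KS01;KS02,
E03,00:00:10,D0,KS01;RR01,
E03,00:00:20,D0,KS01;KS02,
E03,00:00:30,SYNCH,RR01;RR02,
E04,00:00:10,PET,KS01;RR01,
E04,00:00:20,RUB,KS01;RR02,
E04,00:00:30,PET,KS01;RR03,
E04,00:00:40,RUB,KS02;RR01,
E04,00:00:50,PET,KS02;RR02,
E04,00:01:00,RUB,KS01;KS02,
E04,00:01:10,PET,KS01;KS03,
E04,00:01:20,RUB,KS02;KS03,
E04,00:01:30,PET,RR01;RR02,
E04,00:01:40,RUB,RR01;RR03,
E04,00:01:50,D0,KS02;RR03,
E04,00:02:00,D0,KS03;RR01,
E05,00:00:10,D0,KS01;KS02,
E05,00:00:20,D0,KS01;KS03,
E05,00:00:30,SYNCH,KS01;KS02,
E05,00:00:40,SYNCH,KS01;KS03,
E06,00:00:10,PET,KS01;RR01,
E06,00:00:20,D0,KS01;RR02,
E06,00:00:30,D0,KS01;KS02,
E06,00:00:40,D0,RR01;RR02,
E06,00:00:50,SYNCH,KS01;RR01,
E07,00:00:10,PET,KS01;RR01,
E07,00:00:20,RUB,KS01;KS02,
E07,00:00:30,PET,RR01;RR02,
E07,00:00:40,D0,KS01;KS03,
E08,00:00:10,PET,PD01;KS01,
E08,00:00:20,RUB,PD01;KS02,
E08,00:00:30,PET,KS01;KS02,
E08,00:00:40,D0,PD01;KS03,
E08,00:00:50,D0,PD02;KS01,
E08,00:01:00,D0,PD01;PD02,
E08,00:01:10,SYNCH,KS01;KS02,
E09,00:00:10,PET,PD01;KS01,
E09,00:00:20,RUB,PD01;KS02,
E09,00:00:30,PET,PD01;KS03,
E09,00:00:40,RUB,PD02;KS01,
E09,00:00:50,PET,KS01;KS02,
E09,00:01:00,RUB,PD01;PD02,
E09,00:01:10,D0,PD02;KS02,
E09,00:01:20,D0,PD02;KS03,
E09,00:01:30,D0,KS01;KS03,
E09,00:01:40,SYNCH,PD01;KS01,
E09,00:01:50,SYNCH,KS01;KS02,
E09,00:02:00,SYNCH,KS01;KS03,
E09,00:02:10,SYNCH,PD01;PD02,
E10,00:00:10,PET,PD01;RR01,
E10,00:00:20,RUB,PD01;RR02,
E10,00:00:30,D0,PD01;RR03,
E10,00:00:40,D0,PD02;RR01,
E10,00:00:50,D0,PD01;PD02,
E10,00:01:00,D0,RR01;RR02,
E10,00:01:10,SYNCH,PD01;RR01,
E10,00:01:20,SYNCH,PD01;RR02,
E10,00:01:30,SYNCH,RR01;RR02,
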