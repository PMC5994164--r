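((fossil_A:6.24817,extant_01:6.24817):27.6053,((((extant_02:16.1489,fossil_B:16.1489):5.01775,(((extant_03:8.96736,extant_04:8.96736):8.72677,(fossil_C:6.0182,extant_05:6.0182):11.6759):0.798147,fossil_D:18.4923):2.67435):8.02989,(extant_06:26.4269,(extant_07:1.5912,extant_08:1.5912):24.8357):2.76959):2.04466,(extant_09:1.9899,extant_10:1.9899):29.2513):2.61233);
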