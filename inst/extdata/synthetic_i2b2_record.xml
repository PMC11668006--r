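<?xml version="1.0" encoding="UTF-8" ?>
<deIdi2b2>
<TEXT><![CDATA[Record date: 2019-03-04
Seen by Dr. Okafor today. Patient Jane Mills, aged 61, developed a rash after DRUG.
Signed in as jmills99
]]></TEXT>
<TAGS>
<DATE id="P0" start="13" end="23" text="2019-03-04" TYPE="DATE" comment="" />
<NAME id="P1" start="36" end="42" text="Okafor" TYPE="DOCTOR" comment="" />
<NAME id="P2" start="58" end="68" text="Jane Mills" TYPE="PATIENT" comment="" />
<AGE id="P3" start="75" end="77" text="61" TYPE="AGE" comment="" />
<NAME id="P4" start="121" end="129" text="jmills99" TYPE="USERNAME" comment="" />
</TAGS>
</deIdi2b2>

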