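"generic_name","pt"
"risperidone","Extrapyramidal disorder"
"risperidone","Akathisia"
"risperidone","Constipation"
"risperidone","Somnolence"
"risperidone","Dizziness"
"risperidone","Tremor"
"risperidone","Tachycardia"
"risperidone","Dry mouth"
"risperidone","Insomnia"
"risperidone","Weight increased"
"risperidone","Dystonia"
"risperidone","Hypertonia"
"risperidone","Nausea"
"risperidone","Vomiting"
"risperidone","Hyperprolactinaemia"
"risperidone","Amenorrhoea"
"risperidone","Galactorrhoea"
"risperidone","Hepatic function abnormal"
"clozapine","Extrapyramidal disorder"
"clozapine","Akathisia"
"clozapine","Constipation"
"clozapine","Somnolence"
"clozapine","Dizziness"
"clozapine","Tremor"
"clozapine","Tachycardia"
"clozapine","Dry mouth"
"clozapine","Insomnia"
"clozapine","Weight increased"
"clozapine","Dystonia"
"clozapine","Hypertonia"
"clozapine","Nausea"
"clozapine","Vomiting"
"clozapine","White blood cell count decreased"
"clozapine","Drooling"
"clozapine","Hepatic function abnormal"
"olanzapine","Extrapyramidal disorder"
"olanzapine","Akathisia"
"olanzapine","Constipation"
"olanzapine","Somnolence"
"olanzapine","Dizziness"
"olanzapine","Tremor"
"olanzapine","Tachycardia"
"olanzapine","Dry mouth"
"olanzapine","Insomnia"
"olanzapine","Weight increased"
"olanzapine","Dystonia"
"olanzapine","Hypertonia"
"olanzapine","Nausea"
"olanzapine","Vomiting"
"olanzapine","Obesity"
"olanzapine","Blood glucose increased"
"aripiprazole","Extrapyramidal disorder"
"aripiprazole","Akathisia"
"aripiprazole","Constipation"
"aripiprazole","Somnolence"
"aripiprazole","Dizziness"
"aripiprazole","Tremor"
"aripiprazole","Tachycardia"
"aripiprazole","Dry mouth"
"aripiprazole","Insomnia"
"aripiprazole","Weight increased"
"aripiprazole","Dystonia"
"aripiprazole","Hypertonia"
"aripiprazole","Nausea"
"aripiprazole","Vomiting"
"aripiprazole","Headache"
"aripiprazole","Agitation"
"aripiprazole","Anxiety"
"quetiapine","Extrapyramidal disorder"
"quetiapine","Akathisia"
"quetiapine","Constipation"
"quetiapine","Somnolence"
"quetiapine","Dizziness"
"quetiapine","Tremor"
"quetiapine","Tachycardia"
"quetiapine","Dry mouth"
"quetiapine","Insomnia"
"quetiapine","Weight increased"
"quetiapine","Dystonia"
"quetiapine","Hypertonia"
"quetiapine","Nausea"
"quetiapine","Vomiting"
"quetiapine","Orthostatic hypotension"
"quetiapine","Hepatic function abnormal"
"amisulpride","Extrapyramidal disorder"
"amisulpride","Akathisia"
"amisulpride","Constipation"
"amisulpride","Somnolence"
"amisulpride","Dizziness"
"amisulpride","Tremor"
"amisulpride","Tachycardia"
"amisulpride","Dry mouth"
"amisulpride","Insomnia"
"amisulpride","Weight increased"
"amisulpride","Dystonia"
"amisulpride","Hypertonia"
"amisulpride","Nausea"
"amisulpride","Vomiting"
"amisulpride","Hyperprolactinaemia"
"amisulpride","Amenorrhoea"
"amisulpride","Galactorrhoea"
"ziprasidone","Extrapyramidal disorder"
"ziprasidone","Akathisia"
"ziprasidone","Constipation"
"ziprasidone","Somnolence"
"ziprasidone","Dizziness"
"ziprasidone","Tremor"
"ziprasidone","Tachycardia"
"ziprasidone","Dry mouth"
"ziprasidone","Insomnia"
"ziprasidone","Weight increased"
"ziprasidone","Dystonia"
"ziprasidone","Hypertonia"
"ziprasidone","Nausea"
"ziprasidone","Vomiting"
"ziprasidone","Electrocardiogram QT prolonged"
"ziprasidone","Rash"
"perospirone","Extrapyramidal disorder"
"perospirone","Akathisia"
"perospirone","Constipation"
"perospirone","Somnolence"
"perospirone","Dizziness"
"perospirone","Tremor"
"perospirone","Tachycardia"
"perospirone","Dry mouth"
"perospirone","Insomnia"
"perospirone","Weight increased"
"perospirone","Dystonia"
"perospirone","Hypertonia"
"perospirone","Nausea"
"perospirone","Vomiting"
"perospirone","Hepatic function abnormal"
"haloperidol","Extrapyramidal disorder"
"haloperidol","Akathisia"
"haloperidol","Constipation"
"haloperidol","Somnolence"
"haloperidol","Dizziness"
"haloperidol","Tremor"
"haloperidol","Tachycardia"
"haloperidol","Dry mouth"
"haloperidol","Insomnia"
"haloperidol","Weight increased"
"haloperidol","Dystonia"
"haloperidol","Hypertonia"
"haloperidol","Nausea"
"haloperidol","Vomiting"
"haloperidol","Nuchal rigidity"
"haloperidol","Muscle rigidity"
"haloperidol","Electrocardiogram QT prolonged"
"perphenazine","Extrapyramidal disorder"
"perphenazine","Akathisia"
"perphenazine","Constipation"
"perphenazine","Somnolence"
"perphenazine","Dizziness"
"perphenazine","Tremor"
"perphenazine","Tachycardia"
"perphenazine","Dry mouth"
"perphenazine","Insomnia"
"perphenazine","Weight increased"
"perphenazine","Dystonia"
"perphenazine","Hypertonia"
"perphenazine","Nausea"
"perphenazine","Vomiting"
"perphenazine","Tongue induration"
"perphenazine","Orthostatic hypotension"
"sulpiride","Extrapyramidal disorder"
"sulpiride","Akathisia"
"sulpiride","Constipation"
"sulpiride","Somnolence"
"sulpiride","Dizziness"
"sulpiride","Tremor"
"sulpiride","Tachycardia"
"sulpiride","Dry mouth"
"sulpiride","Insomnia"
"sulpiride","Weight increased"
"sulpiride","Dystonia"
"sulpiride","Hypertonia"
"sulpiride","Nausea"
"sulpiride","Vomiting"
"sulpiride","Hyperprolactinaemia"
"sulpiride","Amenorrhoea"
"sulpiride","Galactorrhoea"
"sulpiride","Sinus bradycardia"
"chlorpromazine","Extrapyramidal disorder"
"chlorpromazine","Akathisia"
"chlorpromazine","Constipation"
"chlorpromazine","Somnolence"
"chlorpromazine","Dizziness"
"chlorpromazine","Tremor"
"chlorpromazine","Tachycardia"
"chlorpromazine","Dry mouth"
"chlorpromazine","Insomnia"
"chlorpromazine","Weight increased"
"chlorpromazine","Dystonia"
"chlorpromazine","Hypertonia"
"chlorpromazine","Nausea"
"chlorpromazine","Vomiting"
"chlorpromazine","Blood pressure decreased"
"chlorpromazine","Orthostatic hypotension"
"chlorpromazine","Pruritus"
"chlorpromazine","Rash"
"chlorpromazine","Hepatic function abnormal"
"penfluridol","Extrapyramidal disorder"
"penfluridol","Akathisia"
"penfluridol","Constipation"
"penfluridol","Somnolence"
"penfluridol","Dizziness"
"penfluridol","Tremor"
"penfluridol","Tachycardia"
"penfluridol","Dry mouth"
"penfluridol","Insomnia"
"penfluridol","Weight increased"
"penfluridol","Dystonia"
"penfluridol","Hypertonia"
"penfluridol","Nausea"
"penfluridol","Vomiting"
"chlorprothixene","Extrapyramidal disorder"
"chlorprothixene","Akathisia"
"chlorprothixene","Constipation"
"chlorprothixene","Somnolence"
"chlorprothixene","Dizziness"
"chlorprothixene","Tremor"
"chlorprothixene","Tachycardia"
"chlorprothixene","Dry mouth"
"chlorprothixene","Insomnia"
"chlorprothixene","Weight increased"
"chlorprothixene","Dystonia"
"chlorprothixene","Hypertonia"
"chlorprothixene","Nausea"
"chlorprothixene","Vomiting"
"chlorprothixene","Hypotension"
"droperidol","Extrapyramidal disorder"
"droperidol","Akathisia"
"droperidol","Constipation"
"droperidol","Somnolence"
"droperidol","Dizziness"
"droperidol","Tremor"
"droperidol","Tachycardia"
"droperidol","Dry mouth"
"droperidol","Insomnia"
"droperidol","Weight increased"
"droperidol","Dystonia"
"droperidol","Hypertonia"
"droperidol","Nausea"
"droperidol","Vomiting"
"droperidol","Hypotension"
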